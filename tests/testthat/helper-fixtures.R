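# Shared fixtures: random connectomes, tiny study configs.

# random symmetric correlation matrix with positive and negative entries;
# values rounded to limit accidental near-ties without creating exact ones
random_connectome <- function(n, seed, density = 0.7) {
  set.seed(seed)
  r <- matrix(0, n, n)
  ut <- upper.tri(r)
  vals <- abs(runif(sum(ut), 0.05, 1))
  neg <- runif(sum(ut)) > density
  vals[neg] <- -vals[neg]
  vals[1] <- abs(vals[1])              # at least one retained edge
  r[ut] <- round(vals, 6)
  r <- r + t(r)
  diag(r) <- 1
  functional_connectome(r)
}

ring_filtration <- function(n, ring_r = 0.6, chord_r = 0.2) {
  build_flag_filtration(to_pseudo_distance(fixture_ring_connectome(n, ring_r, chord_r)))
}

# small paired-study config that keeps test runtime low
tiny_config <- function(seed = 1, coupling = 1, n_subjects = 2,
                        conditions = c("rest", "taskA", "taskB"),
                        n_regions = 16) {
  synthetic_study_config(
    n_subjects = n_subjects, n_regions = n_regions,
    n_timepoints_bold = 300, fs_meg = 250, duration_meg = 12,
    conditions = conditions,
    rings = list(list(regions = 1:5, within_rest = 0.3, within_task = 0.6,
                      cross = 0.1),
                 list(regions = 6:10, within_rest = 0.6, within_task = 0.3,
                      cross = 0.1)),
    dc_confound = list(regions = 11:14, r_rest = 0.15, r_task = 0.45),
    coupling_strength = coupling, seed = seed)
}
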