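#' Run the end-to-end bimodal study
#'
#' Executes both processing chains on a synthetic study (or on precomputed
#' connectomes) and compares them:
#' topology — connectome -> pseudo-distance -> flag filtration -> H1 barcode
#' -> volume-optimal cycles -> subject scaffolds -> group-averaged scaffold
#' -> persistence centrality (plus degree centrality per subject, averaged);
#' spectra — MEG-like signals -> IRASA decomposition -> aperiodic band power
#' ratios per subject, averaged per condition; statistics —
#' `compare_modalities()` on the task-minus-rest changes.
#'
#' Subjects are processed independently and every random draw derives from
#' the config seed, so a rerun with the same config reproduces the report
#' exactly.
#'
#' @param config A `synthetic_study_config`.
#' @param band_edges Band scheme for the BPR analysis (default: 32
#'   log-spaced bands over 2-90 Hz).
#' @param component Spectral component for the BPR ("aperiodic" default;
#'   "periodic" reproduces the periodic-control analysis).
#' @param bpr_denominator Full-band reference for the BPR.
#' @param threshold_p Cluster-forming threshold for the permutation test.
#' @param fc_matrices Optional entry point bypassing the BOLD generator: a
#'   list (by condition label) of lists (by subject) of
#'   `functional_connectome`; must cover all conditions.
#' @param out_dir Optional directory; when given, PC/DC/BPR tables and the
#'   report are written as TSV/JSON.
#' @return A `study_report`: list with `pc`, `dc` (per condition
#'   centralities), `bpr` (per condition region x band matrices),
#'   `comparison` (the `modality_report`), `counts` (intervals found,
#'   infinite intervals dropped), and the echoed `config`.
#' @export
run_study <- function(config, band_edges = log_spaced_bands(),
                      component = "aperiodic",
                      bpr_denominator = "total_fullband",
                      threshold_p = 0.05, fc_matrices = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_study_config"))
  conds <- config$conditions
  n <- config$n_regions
  counts <- c(intervals = 0L, infinite_dropped = 0L, zero_discarded = 0L)

  pc <- dc <- bpr <- stats::setNames(vector("list", length(conds)), conds)
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    if (is.null(fc_matrices)) {
      bold <- generate_bold_like(config, cond)
      fcs <- lapply(seq_len(config$n_subjects),
                    function(s) compute_fc(bold, s, cond))
    } else {
      stop_if(!cond %in% names(fc_matrices), "missing condition: ", cond)
      fcs <- fc_matrices[[cond]]
      stop_if(length(fcs) != config$n_subjects,
              "fc_matrices must have one connectome per subject")
    }
    scaffolds <- vector("list", length(fcs))
    dcs <- matrix(NA_real_, length(fcs), n)
    for (s in seq_along(fcs)) {
      topo <- topology_from_fc(fcs[[s]], condition = cond)
      scaffolds[[s]] <- topo$scaffold
      dcs[s, ] <- as.numeric(topo$dc)
      counts["intervals"] <- counts["intervals"] + topo$n_intervals
      counts["infinite_dropped"] <- counts["infinite_dropped"] + topo$n_infinite
      counts["zero_discarded"] <- counts["zero_discarded"] + topo$n_zero
    }
    pc[[cond]] <- persistence_centrality(group_average(scaffolds))
    dc[[cond]] <- centrality(colMeans(dcs), config$regions, kind = "DC")

    meg <- generate_meg_like(config, cond)
    # all subjects side by side: IRASA and the BPR are column-parallel
    xall <- do.call(cbind, lapply(seq_len(config$n_subjects),
                                  function(s) t(meg$data[s, 1L, , ])))
    colnames(xall) <- paste0(rep(seq_len(config$n_subjects),
                                 each = config$n_regions), "_", config$regions)
    dec <- suppressWarnings(irasa(xall, config$fs_meg, hset = config$hset))
    ball <- unclass(band_power_ratio(dec, band_edges, component = component,
                                     denominator = bpr_denominator))
    dim(ball) <- c(config$n_regions, config$n_subjects, ncol(ball))
    b <- colMeans(aperm(ball, c(2L, 1L, 3L)))
    dimnames(b) <- list(config$regions, rownames(band_edges))
    bpr[[cond]] <- structure(b, band_edges = band_edges, component = component,
                             denominator = bpr_denominator,
                             class = "band_power_ratios")
  }

  rest <- conds[1L]; tasks <- conds[-1L]
  comparison <- compare_modalities(pc[[rest]], pc[tasks], dc[[rest]], dc[tasks],
                                   bpr[[rest]], bpr[tasks],
                                   band_edges = band_edges,
                                   threshold_p = threshold_p,
                                   seed = derive_seed(config$seed, 9L))
  report <- structure(list(pc = pc, dc = dc, bpr = bpr,
                           comparison = comparison, counts = counts,
                           config = config), class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' Topology chain for one connectome
#'
#' Connectome -> pseudo-distance -> flag filtration -> H1 barcode ->
#' volume-optimal cycles -> scaffold, plus degree centrality.  This is the
#' per-subject unit of `run_study()` and the precomputed-connectome entry
#' point of the topology chain.
#'
#' @param fc A `functional_connectome`.
#' @param condition Condition label recorded on the scaffold.
#' @return List with `scaffold`, `dc`, `barcode`, `features` and interval
#'   counts (`n_intervals`, `n_infinite`, `n_zero`).
#' @export
topology_from_fc <- function(fc, condition = NA_character_) {
  D <- to_pseudo_distance(fc)
  F <- build_flag_filtration(D)
  bc <- compute_h1_barcode(F)
  feats <- volume_optimal_cycles(F, bc)
  list(scaffold = build_scaffold(feats, length(fc$labels), fc$labels, condition),
       dc = degree_centrality(fc),
       barcode = bc, features = feats,
       n_intervals = sum(is.finite(bc$death)),
       n_infinite = attr(bc, "n_infinite"),
       n_zero = attr(bc, "n_zero_discarded"))
}

write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conds <- report$config$conditions
  cent <- function(lst) do.call(cbind, lapply(lst, as.numeric))
  pc_tab <- cent(report$pc); rownames(pc_tab) <- report$config$regions
  dc_tab <- cent(report$dc); rownames(dc_tab) <- report$config$regions
  write_matrix_tsv(pc_tab, file.path(out_dir, "pc.tsv"))
  write_matrix_tsv(dc_tab, file.path(out_dir, "dc.tsv"))
  for (cond in conds) {
    write_matrix_tsv(unclass(report$bpr[[cond]]),
                     file.path(out_dir, paste0("bpr_", cond, ".tsv")))
  }
  cmp <- report$comparison
  out <- list(conditions = cmp$conditions,
              abs_cos_pc = cmp$abs_cos_pc, abs_cos_dc = cmp$abs_cos_dc,
              tau_rest_vs_dpc = cmp$tau_rest_vs_dpc,
              clusters = if (!is.null(cmp$cluster_test)) cmp$cluster_test$clusters,
              counts = as.list(report$counts),
              seed = report$config$seed)
  jsonlite::write_json(out, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("study report:", x$config$n_subjects, "subjects,",
      length(x$config$conditions), "conditions,", x$config$n_regions,
      "regions\n")
  cat("H1 intervals:", x$counts[["intervals"]], "finite,",
      x$counts[["infinite_dropped"]], "infinite dropped\n")
  print(x$comparison)
  invisible(x)
}
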