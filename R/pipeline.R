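#' Run the end-to-end druggability pipeline over a dataset manifest
#'
#' For every manifest entry: read the structure, obtain the seed ligand
#' (the co-crystallised ligand for ligand-bound entries; for apo and
#' protein/peptide-bound entries the reference complex is read, curated
#' and superposed so its ligand is transferred into the target frame),
#' curate the chain (ligand-proximal chain only, solvent and heteroatoms
#' stripped), detect the binding site, score and classify it. Failures
#' are isolated per structure and logged, never fatal; flat interfaces
#' yield ND records that classify as difficult. The run is deterministic
#' for a fixed manifest and configuration.
#'
#' @param manifest data.frame (or path to a TSV) with columns
#'   `structure_id`, `pdb` (file path), `target`, `form` (`apo`,
#'   `protein_peptide_bound` or `ligand_bound`), `ligand` (residue name of
#'   the seed ligand) and, for non-ligand-bound forms, `reference` (path
#'   to the ligand-bound reference PDB whose `ligand` is transferred).
#' @param config a [pocket_config()].
#' @param scheme classification scheme: `"ppi4"` (four-class PPI scheme)
#'   or `"halgren3"`.
#' @param activities optional data.frame with `structure_id` and `ic50_nM`
#'   used to attach pIC50 values and per-target mean activity.
#' @return object of class `ppidrug_report`: list with `records` (one row
#'   per processed structure), `summary` (per-target statistics, see
#'   [aggregate_target()]), `classification` (per-target class from the
#'   overall median Dscore), `correlations` (Dscore against n, e, p),
#'   `scatter` (per-target mean Dscore vs mean pIC50, when activities are
#'   given) and `log` (one line per manifest entry).
#' @export
ppi_run <- function(manifest, config = pocket_config(),
                    scheme = c("ppi4", "halgren3"), activities = NULL) {
  scheme <- match.arg(scheme)
  if (is.character(manifest)) {
    manifest <- read.delim(manifest, stringsAsFactors = FALSE)
  }
  need <- c("structure_id", "pdb", "target", "form", "ligand")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) .err("ppidrugg_config", paste("manifest is missing:", paste(miss, collapse = ", ")))
  recs <- list()
  logs <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    res <- tryCatch(.process_structure(m, config), error = function(e) e)
    if (inherits(res, "ppidrugg_config")) stop(res) # misconfiguration is fatal
    if (inherits(res, "error")) { # per-structure failures are isolated
      logs[[i]] <- data.frame(
        structure_id = m$structure_id, status = "error",
        message = conditionMessage(res)
      )
    } else {
      recs[[length(recs) + 1]] <- res
      logs[[i]] <- data.frame(
        structure_id = m$structure_id,
        status = if (res$detected) "ok" else "nd",
        message = if (res$detected) {
          sprintf("n=%d dscore=%.3f", res$n, res$dscore)
        } else {
          "no site detected"
        }
      )
    }
  }
  if (!length(recs)) .err("ppidrugg_config", "no structure could be processed")
  records <- do.call(rbind, recs)
  summary <- aggregate_target(records)
  overall <- summary[summary$form == "overall", , drop = FALSE]
  classification <- data.frame(
    target = overall$target,
    median_dscore = overall$median_dscore,
    class = if (scheme == "ppi4") {
      classify_ppi(overall$median_dscore)
    } else {
      classify_halgren(overall$median_dscore)
    },
    stringsAsFactors = FALSE
  )
  correlations <- .descriptor_correlations(records)
  scatter <- .activity_scatter(records, activities)
  structure(list(
    records = records, summary = summary, classification = classification,
    correlations = correlations, scatter = scatter,
    log = do.call(rbind, logs), scheme = scheme, config = config
  ), class = "ppidrug_report")
}

.process_structure <- function(m, config) {
  st <- read_pdb(m$pdb)
  if (m$form == "ligand_bound") {
    lig <- extract_ligand(st, m$ligand)
    st <- strip_non_protein(select_chain(st, lig))
  } else {
    ref_path <- m$reference
    if (is.null(ref_path) || is.na(ref_path) || !nzchar(ref_path)) {
      .err("ppidrugg_config", paste("no reference structure for", m$structure_id))
    }
    ref <- read_pdb(ref_path)
    ref_lig <- extract_ligand(ref, m$ligand)
    ref <- strip_non_protein(select_chain(ref, ref_lig))
    st <- strip_non_protein(st)
    sup <- superpose_on_reference(st, ref, ref_lig)
    st <- sup$target
    lig <- sup$ligand
  }
  sd <- detect_site(st, lig, config)
  druggability_record(m$structure_id, m$target, m$form, sd)
}

.descriptor_correlations <- function(records) {
  det <- records[records$detected, , drop = FALSE]
  out <- list()
  for (v in c("n", "e", "p")) {
    res <- tryCatch(
      pearson_r2(det[[v]], det$dscore, x_name = v, y_name = "dscore"),
      error = function(e) NULL
    )
    if (!is.null(res)) {
      out[[length(out) + 1]] <- data.frame(
        x = v, y = "dscore", r = res$r, r2 = res$r2, n_points = res$n_points
      )
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

.activity_scatter <- function(records, activities) {
  if (is.null(activities)) return(NULL)
  if (!all(c("structure_id", "ic50_nM") %in% names(activities))) {
    .err("ppidrugg_config", "activities needs structure_id and ic50_nM")
  }
  mg <- merge(records, activities, by = "structure_id")
  if (!nrow(mg)) return(NULL)
  mg$pic50 <- pic50(mg$ic50_nM * 1e-9)
  ds <- mg$dscore
  ds[is.na(ds)] <- 0 # ND plotted at zero, the figure convention
  agg <- aggregate(cbind(dscore = ds, pic50 = mg$pic50),
    by = list(target = mg$target), FUN = mean
  )
  agg
}

#' @export
print.ppidrug_report <- function(x, ...) {
  cat(sprintf(
    "<ppidrug_report> %d records, %d targets, scheme %s (%d ND, %d errors)\n",
    nrow(x$records), length(unique(x$records$target)), x$scheme,
    sum(!x$records$detected), sum(x$log$status == "error")
  ))
  invisible(x)
}

#' @export
summary.ppidrug_report <- function(object, ...) {
  cat("Per-target classification (overall median Dscore):\n")
  print(object$classification, row.names = FALSE)
  if (!is.null(object$correlations)) {
    cat("\nDescriptor correlations with Dscore:\n")
    print(object$correlations, row.names = FALSE)
  }
  invisible(object$classification)
}

.fmt_mr <- function(med, lo, hi, digits = 2) {
  ifelse(is.na(med), "ND",
    sprintf(paste0("%.", digits, "f (%.", digits, "f–%.", digits, "f)"), med, lo, hi)
  )
}

#' Write the report tables to a directory
#'
#' Emits `records.tsv`, `target_summary.tsv` (with formatted
#' "median (min-max)" columns alongside the raw statistics),
#' `classification.json`, `correlations.tsv` and
#' `scatter_pic50_dscore.csv` (the latter two only when available).
#'
#' @param report a `ppidrug_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
render_tables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) .err("ppidrugg_io_error", paste("cannot create", dir))
  paths <- character(0)
  w <- function(df, name, sep = "\t") {
    p <- file.path(dir, name)
    write.table(df, p, sep = sep, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  rec <- report$records
  num <- vapply(rec, is.numeric, logical(1))
  rec[num] <- lapply(rec[num], function(v) round(v, 4))
  w(rec, "records.tsv")
  s <- report$summary
  s$dscore_fmt <- .fmt_mr(s$median_dscore, s$min_dscore, s$max_dscore)
  s$n_fmt <- ifelse(is.na(s$median_n), "ND",
    sprintf("%g (%g–%g)", s$median_n, s$min_n, s$max_n)
  )
  s$e_fmt <- .fmt_mr(s$median_e, s$min_e, s$max_e)
  s$p_fmt <- .fmt_mr(s$median_p, s$min_p, s$max_p)
  num <- vapply(s, is.numeric, logical(1))
  s[num] <- lapply(s[num], function(v) round(v, 4))
  w(s, "target_summary.tsv")
  p <- file.path(dir, "classification.json")
  jsonlite::write_json(report$classification, p, auto_unbox = TRUE, digits = NA, na = "null")
  paths <- c(paths, p)
  if (!is.null(report$correlations)) w(report$correlations, "correlations.tsv")
  if (!is.null(report$scatter)) w(report$scatter, "scatter_pic50_dscore.csv", sep = ",")
  invisible(paths)
}
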