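# Asymmetric double sigmoid (ADS) desirability parameters for the eight
# QED descriptors, and the canonical weights, from Bickerton et al. (2012)
# Nature Chemistry 4:90 (supplementary information). Each descriptor x maps
# to d(x) = [A + B/(1+exp(-(x-C+D/2)/E)) * (1 - 1/(1+exp(-(x-C-D/2)/F)))]
# normalised by DMAX, giving a desirability in (0, 1].
.QED_ADS <- data.frame(
  descriptor = c("MW", "ALOGP", "HBA", "HBD", "PSA", "ROTB", "AROM", "ALERTS"),
  column = c("mwt", "logp", "hba", "hbd", "psa", "rotb", "arom_rings", "alerts"),
  A = c(2.817065973, 3.172690585, 2.948620388, 1.618662227, 1.876861559, 0.01, 3.21778897, 0.01),
  B = c(392.5754953, 137.8624751, 160.4605972, 1010.051101, 125.2232657, 272.4121427, 957.7374108, 1199.094025),
  C = c(290.7489764, 2.534937431, 3.615294657, 0.985094388, 62.90773554, 2.55837997, 2.274627939, -0.09002883),
  D = c(2.419764353, 4.581497897, 4.435986202, 1e-09, 87.83366614, 1.565547684, 1e-09, 1e-09),
  E = c(49.22325677, 0.822739154, 0.290141953, 0.713820843, 12.01999824, 1.271567166, 1.317690384, 0.185904477),
  F = c(65.37051707, 0.576295591, 1.300669958, 0.920922555, 28.51324732, 2.758063707, 0.375760881, 0.875193782),
  DMAX = c(104.9805561, 131.3186604, 148.7763046, 258.1632616, 104.5686167, 105.4420403, 312.337261, 417.725314),
  weight = c(0.66, 0.46, 0.05, 0.61, 0.06, 0.65, 0.48, 0.95),
  stringsAsFactors = FALSE
)

#' QED desirability-function parameters
#'
#' The asymmetric-double-sigmoid coefficients and canonical weights of the
#' eight QED descriptors (molecular weight, ALogP, H-bond acceptors and
#' donors, polar surface area, rotatable bonds, aromatic rings, structural
#' alerts), as published by Bickerton et al. (2012).
#'
#' @return data.frame with one row per descriptor.
#' @export
qed_parameters <- function() .QED_ADS

.MOL_COLUMNS <- c("mwt", "hbd", "hba", "logp", "psa", "rotb", "arom_rings", "alerts")

.check_props <- function(props, need) {
  miss <- setdiff(need, names(props))
  if (length(miss)) {
    .err("ppidrugg_invalid", paste("missing property fields:", paste(miss, collapse = ", ")))
  }
  for (cc in need) {
    if (any(is.na(props[[cc]]))) {
      .err("ppidrugg_invalid", paste("NA values in property field:", cc))
    }
  }
  invisible(props)
}

#' Lipinski rule-of-five violation count
#'
#' Number of the four Lipinski conditions violated: Mwt <= 500 Da,
#' LogP <= 5, HBD <= 5, HBA <= 10.
#'
#' @param props data.frame of molecular properties with columns `mwt`,
#'   `hbd`, `hba`, `logp` (one row per molecule).
#' @return integer vector of violation counts (0-4).
#' @examples
#' ro5_violations(data.frame(mwt = 813.43, hbd = 2, hba = 7, logp = 4.9))
#' @export
ro5_violations <- function(props) {
  .check_props(props, c("mwt", "hbd", "hba", "logp"))
  as.integer((props$mwt > 500) + (props$logp > 5) + (props$hbd > 5) + (props$hba > 10))
}

#' Relaxed PPI drug-likeness rule (Ro5-1)
#'
#' A molecule is Ro5-1 drug-like when it has at most one Lipinski
#' violation — the relaxation proposed for PPI inhibitors, whose size and
#' hydrophobicity routinely break one rule while retaining oral activity.
#'
#' @inheritParams ro5_violations
#' @return logical vector.
#' @export
is_druglike_ro5_minus_1 <- function(props) {
  ro5_violations(props) <= 1L
}

.qed_weights <- function(weights) {
  if (is.character(weights)) {
    weights <- match.arg(weights, c("unweighted", "canonical"))
    if (weights == "unweighted") rep(1, 8) else .QED_ADS$weight
  } else {
    if (length(weights) != 8 || any(weights < 0) || all(weights == 0)) {
      .err("ppidrugg_invalid", "weights must be 8 non-negative values, not all zero")
    }
    as.numeric(weights)
  }
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Maps each of the eight descriptors through its published desirability
#' function and returns the weighted geometric mean
#' `exp(sum(w_i log d_i) / sum(w_i))`. The default is the unweighted
#' variant (all weights 1); `weights = "canonical"` selects the published
#' mean weights. Desirabilities are floored at 1e-6 purely as a numeric
#' guard for the logarithm.
#'
#' @param props data.frame with the eight QED descriptor columns `mwt`,
#'   `hbd`, `hba`, `logp`, `psa`, `rotb`, `arom_rings`, `alerts`.
#' @param weights `"unweighted"`, `"canonical"`, or 8 non-negative numbers
#'   (in the descriptor order of [qed_parameters()]).
#' @return numeric vector of QED scores in \[0, 1\].
#' @export
qed_score <- function(props, weights = "unweighted") {
  .check_props(props, .MOL_COLUMNS)
  w <- .qed_weights(weights)
  d <- qed_desirabilities(props)
  exp(as.numeric(log(d) %*% w) / sum(w))
}

#' Per-descriptor QED desirabilities
#'
#' @inheritParams qed_score
#' @return matrix (molecules x 8 descriptors) of desirabilities in (0, 1].
#' @export
qed_desirabilities <- function(props) {
  .check_props(props, .MOL_COLUMNS)
  P <- .QED_ADS
  d <- sapply(seq_len(nrow(P)), function(k) {
    x <- props[[P$column[k]]]
    ads <- P$A[k] + P$B[k] / (1 + exp(-(x - P$C[k] + P$D[k] / 2) / P$E[k])) *
      (1 - 1 / (1 + exp(-(x - P$C[k] - P$D[k] / 2) / P$F[k])))
    pmax(ads / P$DMAX[k], 1e-6)
  })
  d <- matrix(d, ncol = nrow(P), dimnames = list(NULL, P$descriptor))
  d
}

#' Rule-of-Four profile of PPI inhibitors
#'
#' The descriptive profile of known PPI inhibitors: Mwt > 400 Da,
#' ALogP > 4, HBA > 4, rings > 4 (all strict). Not a pass/fail
#' drug-likeness filter but a fingerprint of the chemotype.
#'
#' @param props data.frame with columns `mwt`, `logp`, `hba`,
#'   `arom_rings`.
#' @return data.frame of per-criterion logical flags plus `rule_of_four`
#'   (all four hold).
#' @export
rule_of_four_profile <- function(props) {
  .check_props(props, c("mwt", "logp", "hba", "arom_rings"))
  out <- data.frame(
    mwt_gt_400 = props$mwt > 400,
    logp_gt_4 = props$logp > 4,
    hba_gt_4 = props$hba > 4,
    rings_gt_4 = props$arom_rings > 4
  )
  out$rule_of_four <- out$mwt_gt_400 & out$logp_gt_4 & out$hba_gt_4 & out$rings_gt_4
  if (!is.null(props$id)) out <- cbind(id = props$id, out)
  out
}

#' Per-molecule drug-likeness rule results
#'
#' @inheritParams qed_score
#' @param ro5_max_violations violations tolerated by the strict rule
#'   (default 0: "drug-like" means zero Lipinski violations; set 1 to use
#'   the at-most-one convention).
#' @return data.frame with `violations`, `pass_ro5`, `pass_ro5_minus_1`,
#'   `qed`, `pass_qed` (QED >= 0.5) and `rule_of_four` per molecule.
#' @export
druglikeness_rules <- function(props, weights = "unweighted",
                               ro5_max_violations = 0) {
  v <- ro5_violations(props)
  q <- qed_score(props, weights)
  data.frame(
    id = if (!is.null(props$id)) props$id else seq_along(v),
    violations = v,
    pass_ro5 = v <= ro5_max_violations,
    pass_ro5_minus_1 = v <= 1L,
    qed = q,
    pass_qed = q >= 0.5,
    rule_of_four = rule_of_four_profile(props)$rule_of_four,
    stringsAsFactors = FALSE
  )
}

#' Audit a set of molecules against the drug-likeness rules
#'
#' Counts and percentages (one decimal) of molecules passing the strict
#' Lipinski rule, QED >= 0.5, and the relaxed Ro5-1 rule, optionally
#' grouped by target.
#'
#' @inheritParams druglikeness_rules
#' @param by optional vector of target labels (one per molecule).
#' @return data.frame with one row per group plus an `"all"` row when
#'   grouping, carrying `n`, `n_ro5`, `pct_ro5`, `n_qed`, `pct_qed`,
#'   `n_ro5_minus_1`, `pct_ro5_minus_1`.
#' @export
audit_set <- function(props, by = NULL, weights = "unweighted",
                      ro5_max_violations = 0) {
  if (!nrow(props)) .err("ppidrugg_invalid", "empty property table")
  rules <- druglikeness_rules(props, weights, ro5_max_violations)
  one <- function(r, label) {
    data.frame(
      group = label, n = nrow(r),
      n_ro5 = sum(r$pass_ro5), pct_ro5 = round(100 * mean(r$pass_ro5), 1),
      n_qed = sum(r$pass_qed), pct_qed = round(100 * mean(r$pass_qed), 1),
      n_ro5_minus_1 = sum(r$pass_ro5_minus_1),
      pct_ro5_minus_1 = round(100 * mean(r$pass_ro5_minus_1), 1),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(by)) {
    out <- one(rules, "all")
  } else {
    if (length(by) != nrow(rules)) .err("ppidrugg_invalid", "by must label every molecule")
    parts <- lapply(unique(by), function(g) one(rules[by == g, , drop = FALSE], g))
    out <- rbind(do.call(rbind, parts), one(rules, "all"))
  }
  rownames(out) <- NULL
  out
}
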