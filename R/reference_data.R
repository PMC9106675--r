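#' Published per-target descriptor medians for twelve PPI targets
#'
#' Median Dscore, pocket size (n), enclosure (e) and hydrophilicity (p),
#' with observed ranges and structure counts, for the twelve
#' protein-protein interaction targets of the study this package
#' operationalises (DCN1, Bcl-xL, HDM2, XDM2, Bcl-2, MDMX, HPV E2, Menin,
#' VHL, IL-2, XIAP, ZipA). ZipA's flat interface yielded no detectable
#' site (ND), encoded as `NA`. These values serve as inputs: they
#' parameterise the synthetic emulation of the dataset and anchor the
#' classification examples.
#'
#' @return data.frame with one row per target.
#' @export
reference_targets <- function() {
  df <- read.delim(text = "
target\tn_structures\tmedian_dscore\tdscore_min\tdscore_max\tmedian_n\tn_min\tn_max\tmedian_e\te_min\te_max\tmedian_p\tp_min\tp_max
DCN1\t10\t1.20\t1.14\t1.25\t98\t85\t110\t0.75\t0.71\t0.83\t0.53\t0.46\t0.66
Bcl-xL\t24\t1.01\t0.38\t1.17\t46\t9\t194\t0.71\t0.62\t0.94\t0.49\t0.12\t1.17
HDM2\t87\t1.00\t0.82\t1.33\t54\t20\t105\t0.66\t0.55\t0.82\t0.28\t0.10\t0.52
XDM2\t11\t0.93\t0.83\t1.08\t49\t27\t57\t0.64\t0.62\t0.73\t0.35\t0.12\t0.41
Bcl-2\t26\t0.92\t0.74\t1.19\t46\t20\t104\t0.67\t0.58\t0.78\t0.32\t0.15\t0.53
MDMX\t21\t0.86\t0.76\t1.19\t40\t28\t109\t0.64\t0.58\t0.72\t0.33\t0.06\t0.56
HPV E2\t2\t0.77\t0.70\t0.84\t44\t41\t46\t0.68\t0.66\t0.70\t0.79\t0.59\t0.99
Menin\t34\t0.77\t0.43\t1.02\t48\t17\t100\t0.72\t0.64\t0.79\t0.97\t0.71\t1.13
VHL\t36\t0.68\t0.33\t0.79\t38\t8\t52\t0.60\t0.56\t0.64\t0.82\t0.57\t1.19
IL-2\t14\t0.60\t0.35\t0.80\t24\t10\t55\t0.59\t0.51\t0.80\t0.67\t0.43\t1.15
XIAP\t49\t0.52\t0.23\t0.93\t27\t17\t80\t0.60\t0.50\t0.67\t1.01\t0.72\t1.59
ZipA\t6\tNA\tNA\tNA\tNA\tNA\tNA\tNA\tNA\tNA\tNA\tNA\tNA
", stringsAsFactors = FALSE)
  df
}

#' Published per-form median Dscore and pocket size
#'
#' Median druggability score and pocket size broken down by structural
#' form (apo, protein/peptide-bound, ligand-bound), with sample standard
#' deviations in parentheses in the original table (`NA` where a form is
#' absent, has a single structure, or the site was undetected). The
#' percent-reduction arithmetic of the flexibility analysis operates on
#' these medians.
#'
#' @return data.frame with one row per target x form.
#' @export
reference_form_medians <- function() {
  read.delim(text = "
target\tform\tn_structures\tmedian_dscore\tsd_dscore\tmedian_n\tsd_n
DCN1\tapo\tNA\tNA\tNA\tNA\tNA
DCN1\tprotein_peptide_bound\t2\t1.15\t0.01\t96\t4.24
DCN1\tligand_bound\t8\t1.21\t0.03\t98\t7.87
Bcl-xL\tapo\t4\t0.73\t0.29\t19\t8.73
Bcl-xL\tprotein_peptide_bound\t4\t0.87\t0.10\t32.5\t5.94
Bcl-xL\tligand_bound\t16\t1.09\t0.09\t140\t63.82
HDM2\tapo\t1\t0.93\tNA\t42\tNA
HDM2\tprotein_peptide_bound\t22\t0.97\t0.06\t52\t11.11
HDM2\tligand_bound\t64\t1.03\t0.11\t55\t16.35
XDM2\tapo\tNA\tNA\tNA\tNA\tNA
XDM2\tprotein_peptide_bound\t1\t0.85\tNA\t27\tNA
XDM2\tligand_bound\t10\t0.93\t0.08\t50.5\t7.84
Bcl-2\tapo\tNA\tNA\tNA\tNA\tNA
Bcl-2\tprotein_peptide_bound\t9\t0.84\t0.06\t30\t11.86
Bcl-2\tligand_bound\t17\t0.97\t0.10\t50\t17.00
MDMX\tapo\tNA\tNA\tNA\tNA\tNA
MDMX\tprotein_peptide_bound\t11\t0.90\t0.07\t40\t7.27
MDMX\tligand_bound\t10\t0.85\t0.13\t36.5\t24.70
HPV E2\tapo\t1\t0.70\tNA\t41\tNA
HPV E2\tprotein_peptide_bound\tNA\tNA\tNA\tNA\tNA
HPV E2\tligand_bound\t1\t0.84\tNA\t46\tNA
Menin\tapo\t1\t0.79\tNA\t45\tNA
Menin\tprotein_peptide_bound\t4\t0.88\t0.10\t71\t19.16
Menin\tligand_bound\t29\t0.76\t0.10\t46\t17.20
VHL\tapo\tNA\tNA\tNA\tNA\tNA
VHL\tprotein_peptide_bound\t5\t0.62\t0.13\t29\t13.20
VHL\tligand_bound\t31\t0.69\t0.10\t39\t10.62
IL-2\tapo\t4\t0.48\t0.19\t21.5\t6.85
IL-2\tprotein_peptide_bound\t4\t0.48\t0.07\t19.5\t6.70
IL-2\tligand_bound\t6\t0.72\t0.12\t30.5\t13.02
XIAP\tapo\t2\t0.31\t0.11\t17\t0
XIAP\tprotein_peptide_bound\t15\t0.52\t0.04\t26\t4.26
XIAP\tligand_bound\t32\t0.52\t0.14\t28\t16.35
ZipA\tapo\t1\tNA\tNA\tNA\tNA
ZipA\tprotein_peptide_bound\t1\tNA\tNA\tNA\tNA
ZipA\tligand_bound\t4\tNA\tNA\tNA\tNA
", stringsAsFactors = FALSE)
}
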