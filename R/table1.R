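#' Packaged per-tumor detection score table
#'
#' The published 13-tumor score table shipped with the package as a
#' plain-TSV fixture: per tumor and per modality (T1, T2, T1+T2, PET,
#' MRI+PET, plus an `Optical` row carrying the ground-truth volume), the
#' segmented volume (mm^3), sensitivity, specificity, Dice coefficient and
#' maximum surface distance (mm; `NA` where the tumor was not detected at
#' all — printed as "nd"), with the xenograft cell line and gadolinium
#' enhancement status. Strata: 4 Gd+ tumors, 9 Gd- of which 5 are
#' PET-visible.
#'
#' @return data.frame with 78 rows (13 tumors x 6 modality rows).
#' @examples
#' tab <- table1_fixture()
#' median(tab$sensitivity[tab$modality == "PET"]) # 0.67
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_scores.tsv", package = "tumorburden")
  if (path == "") stop("fixture table1_scores.tsv not found; is the package installed?")
  tab <- utils::read.delim(path,
    sep = "\t", stringsAsFactors = FALSE,
    na.strings = "nd", check.names = FALSE
  )
  tab$gd_status <- as.logical(tab$gd_status)
  tab
}
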