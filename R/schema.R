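#' Feature schema for longitudinal AD cohorts
#'
#' A feature schema fixes the names, kinds and column order of the variables a
#' cohort carries: exactly one categorical variable (the clinical diagnosis,
#' levels NC/MCI/AD) and 22 continuous markers. Internally a subject's data
#' matrix has 25 columns: three one-hot diagnosis columns followed by the 22
#' continuous markers; the observation mask has 23 columns (the diagnosis mask
#' counted once).
#'
#' @param names character vector of 23 variable names; the categorical variable
#'   must be named `"DX"`.
#' @param units optional character vector of units, same length as `names`.
#' @return an object of class `feature_schema`.
#' @seealso [adni_schema()] for the standard 23-variable TADPOLE set.
#' @export
feature_schema <- function(names, units = NULL) {
  stopifnot(is.character(names), length(names) == 23L)
  if (sum(names == "DX") != 1L)
    stop("schema must contain exactly one categorical variable named 'DX'")
  if (anyDuplicated(names))
    stop("schema variable names must be unique")
  # canonical order: DX first, then the continuous markers in given order
  cont <- names[names != "DX"]
  structure(
    list(names = c("DX", cont),
         continuous = cont,
         units = units),
    class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("Feature schema: DX (NC/MCI/AD) + ", length(x$continuous),
      " continuous markers\n", sep = "")
  cat("  ", paste(x$continuous, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Reference marginals for the standard TADPOLE variable set: population mean,
# population sd, and the fraction of subject-visits at which the variable is
# actually observed in ADNI-like data. Used as simulator anchors and as the
# default missingness rates.
.adni_reference <- function() {
  tab <- data.frame(
    name = c("CDRSB", "ADAS11", "ADAS13", "MMSE",
             "RAVLT_immediate", "RAVLT_learning", "RAVLT_forgetting",
             "RAVLT_perc_forgetting", "FAQ", "MOCA",
             "Ventricles", "Hippocampus", "WholeBrain", "Entorhinal",
             "Fusiform", "MidTemp", "ICV",
             "AV45", "FDG", "ABETA", "TAU", "PTAU"),
    mean = c(2.17, 11.3, 17.5, 26.5,
             34.4, 4.02, 4.23,
             59.7, 5.59, 23.0,
             4.21e4, 6.68e3, 1.01e6, 3.44e3,
             1.71e4, 1.92e4, 1.53e6,
             1.19, 1.20, 1.02e3, 2.93e2, 48.0),
    sd = c(2.81, 8.6, 11.6, 3.9,
           13.6, 2.81, 2.52,
           38.3, 7.92, 4.7,
           2.32e4, 1.24e3, 1.1e5, 0.81e3,
           0.28e4, 0.31e4, 1.6e5,
           0.22, 0.16, 0.59e3, 1.30e2, 14.4),
    observed = c(0.7036, 0.6995, 0.6927, 0.7012,
                 0.6933, 0.6933, 0.6912,
                 0.6857, 0.7060, 0.3899,
                 0.5844, 0.5339, 0.6035, 0.5078,
                 0.5078, 0.5078, 0.6243,
                 0.1662, 0.2631, 0.1860, 0.1855, 0.1862),
    # direction of change as disease stage advances: +1 increases, -1
    # decreases, 0 stage-independent (head size)
    direction = c(+1, +1, +1, -1,
                  -1, -1, +1,
                  +1, +1, -1,
                  +1, -1, -1, -1,
                  -1, -1, 0,
                  +1, -1, -1, +1, +1),
    stringsAsFactors = FALSE)
  rownames(tab) <- tab$name
  tab
}

#' Standard 23-variable schema (TADPOLE recommended set)
#'
#' Clinical diagnosis plus 22 continuous markers: cognitive/functional scores
#' (CDRSB, ADAS-Cog11/13, MMSE, RAVLT subscores, FAQ, MOCA), T1 MRI volumes
#' (ventricles, hippocampus, whole brain, entorhinal, fusiform, middle
#' temporal, intracranial), PET measures (AV45, FDG) and CSF markers
#' (beta-amyloid, total tau, phosphorylated tau).
#'
#' @return a `feature_schema` with 23 variables, diagnosis first.
#' @export
adni_schema <- function() {
  feature_schema(c("DX", .adni_reference()$name))
}

#' Diagnosis labels and one-hot encoding
#'
#' Diagnosis is encoded as a length-3 vector: first entry 1 for a normal
#' control (NC), second for mild cognitive impairment (MCI), third for AD
#' dementia. A missing label yields a vector of `NA`s so that the caller can
#' mask it.
#'
#' @param label one of `"NC"`, `"MCI"`, `"AD"`, or `NA` for missing.
#' @return numeric 3-vector, one-hot or all-`NA`.
#' @examples
#' one_hot_diagnosis("NC")   # c(1, 0, 0)
#' one_hot_diagnosis("AD")   # c(0, 0, 1)
#' @export
one_hot_diagnosis <- function(label) {
  if (length(label) != 1L) stop("one label at a time")
  if (is.na(label)) return(rep(NA_real_, 3L))
  i <- match(label, dx_levels())
  if (is.na(i)) stop("unknown diagnosis label: '", label,
                     "' (expected NC, MCI or AD)")
  v <- numeric(3L)
  v[i] <- 1
  v
}

#' @rdname one_hot_diagnosis
#' @export
dx_levels <- function() c("NC", "MCI", "AD")

# column bookkeeping for the 25-column value matrix / 23-column mask
.n_dx <- 3L
.n_cont <- 22L
.dx_cols <- 1:3
.cont_cols <- function() 3L + seq_len(.n_cont)
# mask columns: 1 = diagnosis, 2..23 = continuous markers
.mask_cont_cols <- function() 1L + seq_len(.n_cont)

# expand a 23-column mask to the 25 value columns (diagnosis mask repeated 3x)
.expand_mask <- function(obs23) {
  cbind(obs23[, 1L], obs23[, 1L], obs23[, 1L], obs23[, -1L, drop = FALSE])
}
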