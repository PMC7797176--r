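#' Build a subject's fixed-interval grid from raw visits
#'
#' Discretizes a subject's visit timeline onto a grid with slots every
#' `resolution` months, the subject's first visit defining month 0. Each visit
#' is assigned to the nearest slot. When two visits land on the same slot
#' (possible at coarse resolutions), the visit nearer the slot takes priority
#' (ties: the earlier visit) and observed features of the lower-priority visit
#' that the winner did not observe are merged in, so no disjoint observation
#' is lost.
#'
#' @param visits data.frame with a `month` column (numeric, possibly
#'   off-schedule), a `DX` column (character NC/MCI/AD or `NA`) and one column
#'   per continuous marker in `schema` (numeric, `NA` = missing).
#' @param schema a [feature_schema()].
#' @param resolution grid interval in months: 1, 3 or 6.
#' @param subject_id identifier stored on the trajectory.
#' @return an object of class `subject_trajectory` with elements
#'   `grid_months` (slot months, 0-based), `values` (T x 25 matrix: 3 one-hot
#'   diagnosis columns then 22 markers, `NA` where unobserved), `observed`
#'   (T x 23 logical mask, diagnosis counted once) and `visit_record` (the
#'   original months with their assigned slots).
#' @export
build_monthly_grid <- function(visits, schema, resolution = 1L,
                               subject_id = "s") {
  if (!resolution %in% c(1L, 3L, 6L))
    stop("resolution must be 1, 3 or 6 months")
  if (nrow(visits) < 1L) stop("at least one visit is required")
  visits <- visits[order(visits$month), , drop = FALSE]
  orig_months <- visits$month
  rel <- orig_months - orig_months[1L]
  # nearest slot; exact midpoints resolve to the earlier slot
  slot_idx <- as.integer(ceiling(rel / resolution - 0.5))
  n_slots <- max(slot_idx) + 1L
  grid_months <- (seq_len(n_slots) - 1L) * resolution

  values <- matrix(NA_real_, n_slots, .n_dx + .n_cont)
  observed <- matrix(FALSE, n_slots, 1L + .n_cont)
  colnames(observed) <- c("DX", schema$continuous)

  # assignment priority: distance to slot, then earlier visit
  dist <- abs(rel - slot_idx * resolution)
  ord <- order(slot_idx, dist, seq_along(slot_idx))
  for (i in ord) {
    s <- slot_idx[i] + 1L
    dx <- visits$DX[i]
    if (!is.na(dx) && !observed[s, 1L]) {
      values[s, .dx_cols] <- one_hot_diagnosis(dx)
      observed[s, 1L] <- TRUE
    }
    for (j in seq_len(.n_cont)) {
      v <- visits[[schema$continuous[j]]][i]
      if (!is.na(v) && !observed[s, 1L + j]) {
        values[s, 3L + j] <- v
        observed[s, 1L + j] <- TRUE
      }
    }
  }

  structure(
    list(subject_id = as.character(subject_id),
         resolution = as.integer(resolution),
         grid_months = grid_months,
         values = values,
         observed = observed,
         visit_record = data.frame(month = orig_months,
                                   slot = slot_idx + 1L)),
    class = "subject_trajectory")
}

#' @export
print.subject_trajectory <- function(x, ...) {
  cat("<subject_trajectory> ", x$subject_id, ": ",
      nrow(x$visit_record), " visits on a ", length(x$grid_months),
      "-slot grid (", x$resolution, "-month interval), ",
      sum(x$observed), " observed entries\n", sep = "")
  invisible(x)
}

#' Assemble a cohort from subject trajectories
#'
#' @param subjects list of [build_monthly_grid()] trajectories.
#' @param schema the shared [feature_schema()].
#' @return an object of class `ad_cohort`; subjects are sorted by ID.
#' @export
cohort <- function(subjects, schema = adni_schema()) {
  ids <- vapply(subjects, function(s) s$subject_id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate subject IDs in cohort")
  subjects <- subjects[order(ids)]
  names(subjects) <- sort(ids)
  res <- if (length(subjects)) subjects[[1L]]$resolution else 1L
  structure(
    list(subjects = subjects, schema = schema, resolution = res,
         normalized = FALSE, norm_stats = NULL),
    class = "ad_cohort")
}

#' @export
print.ad_cohort <- function(x, ...) {
  nv <- vapply(x$subjects, function(s) nrow(s$visit_record), integer(1L))
  cat("<ad_cohort> ", length(x$subjects), " subjects, ",
      sum(nv), " visits (mean ",
      if (length(nv)) round(mean(nv), 2) else 0, "/subject), ",
      x$resolution, "-month grid",
      if (x$normalized) ", z-normalized" else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.ad_cohort <- function(x) length(x$subjects)

#' Subset a cohort by subject IDs
#' @param x an `ad_cohort`; @param ids character vector of subject IDs.
#' @export
cohort_subset <- function(x, ids) {
  missing_ids <- setdiff(ids, names(x$subjects))
  if (length(missing_ids))
    stop("unknown subject IDs: ", paste(missing_ids, collapse = ", "))
  out <- x
  out$subjects <- x$subjects[sort(ids)]
  out
}

#' Read a long-format longitudinal CSV into a cohort
#'
#' Expected columns: `subject_id`, `month`, `DX`, and the 22 continuous marker
#' columns of `schema`. Empty cells are missing. Rows with no observed
#' variable at all are dropped; subjects are sorted by ID.
#'
#' @param path CSV file path.
#' @param schema a [feature_schema()].
#' @param resolution grid interval in months (passed to
#'   [build_monthly_grid()]).
#' @return an `ad_cohort`.
#' @export
read_cohort <- function(path, schema = adni_schema(), resolution = 1L) {
  if (file.size(path) == 0L) return(cohort(list(), schema))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  if (nrow(df) == 0L) return(cohort(list(), schema))
  expected <- c("subject_id", "month", "DX", schema$continuous)
  unknown <- setdiff(names(df), expected)
  if (length(unknown))
    stop("unknown column(s) in cohort CSV: ", paste(unknown, collapse = ", "))
  absent <- setdiff(expected, names(df))
  if (length(absent))
    stop("missing column(s) in cohort CSV: ", paste(absent, collapse = ", "))
  df$DX[!is.na(df$DX) & df$DX == ""] <- NA_character_
  bad_dx <- setdiff(unique(df$DX[!is.na(df$DX)]), dx_levels())
  if (length(bad_dx))
    stop("invalid diagnosis label(s): ", paste(bad_dx, collapse = ", "),
         " (expected NC, MCI or AD)")
  for (v in schema$continuous) {
    if (!is.numeric(df[[v]])) {
      suppressWarnings(num <- as.numeric(ifelse(df[[v]] == "", NA, df[[v]])))
      bad <- which(!is.na(df[[v]]) & df[[v]] != "" & is.na(num))
      if (length(bad))
        stop("non-numeric value for '", v, "' at row ", bad[1L])
      df[[v]] <- num
    }
  }
  any_obs <- !is.na(df$DX)
  for (v in schema$continuous) any_obs <- any_obs | !is.na(df[[v]])
  df <- df[any_obs, , drop = FALSE]
  if (nrow(df) == 0L) return(cohort(list(), schema))

  subjects <- lapply(split(df, df$subject_id), function(d)
    build_monthly_grid(d, schema, resolution, subject_id = d$subject_id[1L]))
  cohort(unname(subjects), schema)
}

#' Read the TADPOLE spreadsheet dialect
#'
#' Thin column-mapping layer: `RID` -> `subject_id`, `Month_bl` -> `month`,
#' and diagnosis labels `NL`/`Dementia` -> `NC`/`AD` (labels already `NC`,
#' `MCI`, `AD` pass through).
#'
#' @inheritParams read_cohort
#' @export
read_cohort_tadpole <- function(path, schema = adni_schema(),
                                resolution = 1L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("RID" %in% names(df)) names(df)[names(df) == "RID"] <- "subject_id"
  if ("Month_bl" %in% names(df)) names(df)[names(df) == "Month_bl"] <- "month"
  if ("DX" %in% names(df)) {
    df$DX[df$DX %in% c("NL", "CN")] <- "NC"
    df$DX[df$DX == "Dementia"] <- "AD"
  }
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(df, tmp, row.names = FALSE, na = "")
  read_cohort(tmp, schema, resolution)
}

#' Write a cohort back to the long CSV dialect
#'
#' Emits one row per grid slot carrying at least one observation, ordered by
#' subject ID then month (bit-stable ordering).
#'
#' @param x an `ad_cohort`; @param path output CSV path.
#' @export
write_cohort <- function(x, path) {
  rows <- lapply(x$subjects, function(s) {
    keep <- which(rowSums(s$observed) > 0L)
    if (!length(keep)) return(NULL)
    dx <- rep(NA_character_, length(keep))
    obs_dx <- s$observed[keep, 1L]
    dx[obs_dx] <- dx_levels()[max.col(s$values[keep, .dx_cols, drop = FALSE],
                                      ties.method = "first")][obs_dx]
    g <- s$values[keep, .cont_cols(), drop = FALSE]
    colnames(g) <- x$schema$continuous
    data.frame(subject_id = s$subject_id, month = s$grid_months[keep],
               DX = dx, g, check.names = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df))
    df <- data.frame(subject_id = character(), month = numeric(),
                     DX = character())
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Normalization statistics from training subjects
#'
#' Per-continuous-feature mean and standard deviation over all observed
#' entries, pooling subjects and timepoints. Diagnosis is categorical and
#' excluded.
#'
#' @param x an `ad_cohort` (training subjects only).
#' @return object of class `norm_stats` with `mean` and `sd` vectors (length
#'   22, named by marker).
#' @export
fit_norm_stats <- function(x) {
  vals <- do.call(rbind, lapply(x$subjects, function(s)
    s$values[, .cont_cols(), drop = FALSE]))
  if (is.null(vals) || nrow(vals) == 0L) stop("empty training cohort")
  m <- colMeans(vals, na.rm = TRUE)
  s <- apply(vals, 2L, stats::sd, na.rm = TRUE)
  names(m) <- names(s) <- x$schema$continuous
  bad <- which(is.na(s) | s == 0)
  if (length(bad))
    stop("constant or never-observed feature(s): ",
         paste(x$schema$continuous[bad], collapse = ", "))
  structure(list(mean = m, sd = s), class = "norm_stats")
}

#' z-normalize / denormalize a cohort
#'
#' Continuous entries are replaced by `(x - mean) / sd` using statistics
#' estimated on training subjects; one-hot diagnosis columns and the
#' observation masks are untouched. `denormalize()` inverts the map.
#'
#' @param x an `ad_cohort`; @param stats a [fit_norm_stats()] object.
#' @export
znormalize <- function(x, stats) {
  x$subjects <- lapply(x$subjects, function(s) {
    g <- s$values[, .cont_cols(), drop = FALSE]
    s$values[, .cont_cols()] <- sweep(sweep(g, 2L, stats$mean), 2L, stats$sd,
                                      "/")
    s
  })
  x$normalized <- TRUE
  x$norm_stats <- stats
  x
}

#' @rdname znormalize
#' @export
denormalize <- function(x, stats) {
  x$subjects <- lapply(x$subjects, function(s) {
    g <- s$values[, .cont_cols(), drop = FALSE]
    s$values[, .cont_cols()] <- sweep(sweep(g, 2L, stats$sd, "*"), 2L,
                                      stats$mean, "+")
    s
  })
  x$normalized <- FALSE
  x
}

# denormalize a 22-row matrix of continuous predictions (features x months)
.denorm_cont <- function(g, stats) g * stats$sd + stats$mean

#' Repeated train/validation/test split plans
#'
#' Subject IDs are permuted once by `seed` and the permutation is tiled into
#' disjoint test blocks of 1/20 of the cohort, so the train:validation:test
#' subject ratio is 18:1:1 in every repeat; with `n_repeats = 20` the test
#' blocks cover the whole cohort. Within each repeat the non-test subjects are
#' split 18:1 into train and validation.
#'
#' @param x an `ad_cohort`; @param n_repeats number of repeats (at most 20);
#' @param seed integer seed for the permutation.
#' @return list of `n_repeats` plans, each with `train`, `val`, `test` ID
#'   vectors and the repeat index.
#' @export
make_split_plan <- function(x, n_repeats = 20L, seed = 1L) {
  n <- length(x$subjects)
  if (n_repeats > 20L)
    stop("at most 20 repeats: test blocks of 1/20 cannot tile further")
  block <- floor(n / 20)
  if (block < 1L)
    stop("cohort too small: ", n, " subjects cannot fill 1/20 test blocks")
  ids <- names(x$subjects)
  perm <- ids[.with_seed(seed, sample.int(n))]
  lapply(seq_len(n_repeats), function(k) {
    test <- perm[((k - 1L) * block + 1L):(k * block)]
    rest <- setdiff(perm, test)
    n_val <- max(1L, round(length(rest) / 19))
    val <- rest[seq_len(n_val)]
    train <- rest[-seq_len(n_val)]
    list(repeat_index = k, train = train, val = val, test = test)
  })
}

#' Input/target timepoint partition for a held-out subject
#'
#' The first half of a subject's visit timepoints (grid slots carrying at
#' least one observation) are used as inputs and the second half as
#' forecasting targets; with an odd count the extra timepoint goes to the
#' input side. A single-visit subject gets that visit as input and no
#' targets.
#'
#' @param traj a `subject_trajectory`.
#' @return list with integer slot vectors `input_slots` and `target_slots`.
#' @export
split_timepoints <- function(traj) {
  visit_slots <- which(rowSums(traj$observed) > 0L)
  n_in <- ceiling(length(visit_slots) / 2)
  list(input_slots = visit_slots[seq_len(n_in)],
       target_slots = if (n_in < length(visit_slots))
         visit_slots[(n_in + 1L):length(visit_slots)] else integer(0L))
}

# run expr with a local RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
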