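# Population-level aggregation of per-cell measurements: the heatmaps, box
# summaries, correlations and group tests reported for chromosome-territory
# populations, plus the translocation screen.

#' Aggregate per-cell measurements into a population summary
#'
#' Heatmap entries are medians over cells (median-of-cells, not pooled
#' voxels); contact and pairing entries are frequencies (fraction of cells
#' `TRUE`). Missing per-cell fields are excluded entry-wise, with the
#' remaining `n` reported per entry.
#'
#' @param cells tibble from [measure_cells()] (one row per cell).
#' @param channels channels to aggregate; default: inferred from `volfrac_*`
#'   columns, probe channels (`cen`, `mid`, `tel`) excluded.
#' @return object of class `ct_summary`: `overlap` (matrix, `[A, B]` =
#'   median `O(A|B)`), `overlap_n`, `contact` (symmetric off-diagonal
#'   contact frequencies, per-channel pairing frequency on the diagonal),
#'   `contact_n`, `shell_profiles` (tibble of mean shell fractions),
#'   `volume` (tibble of per-channel volume summaries), `config`
#'   (configuration frequencies or `NULL`), `n_cells`.
#' @export
aggregate_cells <- function(cells, channels = NULL) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1L)
  if (is.null(channels)) {
    channels <- sub("^volfrac_", "", grep("^volfrac_", names(cells), value = TRUE))
    channels <- setdiff(channels, c("cen", "mid", "tel"))
  }
  nch <- length(channels)
  ov <- matrix(NA_real_, nch, nch, dimnames = list(channels, channels))
  ovn <- matrix(0L, nch, nch, dimnames = list(channels, channels))
  ct <- matrix(NA_real_, nch, nch, dimnames = list(channels, channels))
  ctn <- matrix(0L, nch, nch, dimnames = list(channels, channels))
  col_or_null <- function(nm) if (nm %in% names(cells)) cells[[nm]] else NULL
  pair_col <- function(prefix, a, b, sep = "_") {
    col_or_null(paste0(prefix, a, sep, b))
  }
  for (a in channels) for (b in channels) {
    if (a == b) {
      v <- col_or_null(paste0("paired_", a))
      if (!is.null(v)) {
        ct[a, a] <- mean(v, na.rm = TRUE)
        ctn[a, a] <- sum(!is.na(v))
      }
    } else {
      v <- col_or_null(paste0("ovf_", a, "_given_", b))
      if (!is.null(v)) {
        ov[a, b] <- median(v, na.rm = TRUE)
        ovn[a, b] <- sum(!is.na(v))
      }
      cc <- pair_col("contact_", a, b) %||% pair_col("contact_", b, a)
      if (!is.null(cc)) {
        ct[a, b] <- mean(cc, na.rm = TRUE)
        ctn[a, b] <- sum(!is.na(cc))
      }
    }
  }
  shell_cols <- grep("^shell[0-9]+_", names(cells), value = TRUE)
  shell_profiles <- NULL
  if (length(shell_cols)) {
    shell_profiles <- tidyr::pivot_longer(
      cells[, c("cell_id", shell_cols)], -"cell_id",
      names_pattern = "^shell([0-9]+)_(.*)$",
      names_to = c("shell", "channel"), values_to = "fraction"
    )
    shell_profiles <- dplyr::summarise(
      dplyr::group_by(shell_profiles,
                      .data$channel, shell = as.integer(.data$shell)),
      mean_fraction = mean(.data$fraction, na.rm = TRUE),
      n = sum(!is.na(.data$fraction)), .groups = "drop"
    )
    shell_profiles <- shell_profiles[shell_profiles$channel %in% channels, ]
  }
  volume <- dplyr::bind_rows(lapply(channels, function(ch) {
    v <- col_or_null(paste0("volfrac_", ch))
    if (is.null(v)) return(NULL)
    ts <- tukey_summary(v[!is.na(v)])
    tibble::tibble(channel = ch, median_volfrac = ts$median,
                   q1 = ts$q1, q3 = ts$q3, n = sum(!is.na(v)))
  }))
  config <- NULL
  if ("cfg_state" %in% names(cells) && any(!is.na(cells$cfg_state))) {
    config <- configuration_frequencies(cells$cfg_state)
  }
  structure(
    list(overlap = ov, overlap_n = ovn, contact = ct, contact_n = ctn,
         shell_profiles = shell_profiles, volume = volume, config = config,
         channels = channels, n_cells = nrow(cells)),
    class = "ct_summary"
  )
}

#' @export
print.ct_summary <- function(x, ...) {
  cat(sprintf("<ct_summary> %d cells, channels: %s\n", x$n_cells,
              paste(x$channels, collapse = ", ")))
  cat("median overlap O(row|col):\n")
  print(round(x$overlap, 3))
  cat("contact frequencies (diagonal = pairing):\n")
  print(round(x$contact, 3))
  invisible(x)
}

#' @export
tidy.ct_summary <- function(x, ...) {
  long <- function(m, nm, what) {
    g <- expand.grid(row = rownames(m), col = colnames(m),
                     stringsAsFactors = FALSE)
    tibble::tibble(metric = what, channel_a = g$row, channel_b = g$col,
                   value = as.vector(m), n = as.vector(nm))
  }
  out <- dplyr::bind_rows(
    long(x$overlap, x$overlap_n, "median_overlap"),
    long(x$contact, x$contact_n, "contact_frequency")
  )
  out[!(out$metric == "median_overlap" & out$channel_a == out$channel_b), ]
}

#' @export
glance.ct_summary <- function(x, ...) {
  tibble::tibble(
    n_cells = x$n_cells,
    n_channels = length(x$channels),
    median_pairing = median(diag(x$contact), na.rm = TRUE),
    median_overlap = median(x$overlap[row(x$overlap) != col(x$overlap)],
                            na.rm = TRUE)
  )
}

#' Coefficient of determination of a least-squares line
#'
#' @param x,y numeric vectors of equal length `>= 3`; `x` must not be
#'   constant. A constant `y` is defined to give 0.
#' @return R^2 in `[0, 1]`.
#' @export
r_squared <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("`x` is constant", call. = FALSE)
  syy <- sum((y - mean(y))^2)
  if (syy == 0) return(0)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy^2 / (sxx * syy)
}

#' Tukey five-number summary with outliers
#'
#' Quartiles use the linear-interpolation convention
#' (`stats::quantile(type = 7)`); whiskers reach the most extreme data
#' within `1.5 * IQR` of the quartiles, points beyond are outliers.
#'
#' @param values numeric vector, `n >= 1`.
#' @return list: `min`, `q1`, `median`, `q3`, `max`, `whisker_low`,
#'   `whisker_high`, `outliers`, `n`.
#' @export
tukey_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 1L) stop("no finite values", call. = FALSE)
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(min = min(values), q1 = q[1], median = q[2], q3 = q[3],
       max = max(values),
       whisker_low = min(values[inside]), whisker_high = max(values[inside]),
       outliers = sort(values[!inside]), n = length(values))
}

#' Two-group comparison
#'
#' `rank_sum` is the two-sided Mann-Whitney/Wilcoxon rank-sum test on two
#' value vectors; `fisher_2x2` is Fisher's exact test on a 2x2 count table
#' (pass the table as `a`, leave `b` missing); `t_test` is Welch's t-test.
#' Routine statistics are delegated to [stats::wilcox.test()],
#' [stats::fisher.test()] and [stats::t.test()].
#'
#' @param a numeric values of group A, or a 2x2 matrix of counts for
#'   `fisher_2x2`.
#' @param b numeric values of group B (ignored for `fisher_2x2`).
#' @param kind `"rank_sum"`, `"fisher_2x2"` or `"t_test"`.
#' @return tibble: `kind`, `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b = NULL, kind = c("rank_sum", "fisher_2x2", "t_test")) {
  kind <- match.arg(kind)
  if (kind == "fisher_2x2") {
    stopifnot(is.matrix(a), all(dim(a) == c(2L, 2L)))
    ft <- fisher.test(a, alternative = "two.sided")
    return(tibble::tibble(kind = kind, statistic = unname(ft$estimate),
                          p_value = ft$p.value,
                          n_a = sum(a[1, ]), n_b = sum(a[2, ])))
  }
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) stop("empty group", call. = FALSE)
  ht <- if (kind == "rank_sum") {
    suppressWarnings(wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                                 correct = TRUE))
  } else {
    t.test(a, b, alternative = "two.sided")
  }
  tibble::tibble(kind = kind, statistic = unname(ht$statistic),
                 p_value = ht$p.value, n_a = length(a), n_b = length(b))
}

#' Screen a population for translocation-like overlap elevation
#'
#' A stable translocation joins material of one chromosome to another, which
#' shows up in interphase as a persistently elevated pairwise overlap. The
#' screen flags channel pairs whose median overlap (mean of the two directed
#' medians) exceeds `fold_threshold` times the median over all pairs.
#'
#' Both conditions must hold to flag: the pair's median overlap exceeds
#' `fold_threshold` times the median over all pairs, *and* exceeds the
#' absolute floor `min_overlap`. The floor keeps the screen stable when
#' baseline overlaps are near zero (a fold ratio of two tiny medians is
#' noise, and overlap below ~10% is within the normal range of abutting
#' territories).
#'
#' @param summary a [aggregate_cells()] result (`ct_summary`).
#' @param fold_threshold fold-elevation above the median pair.
#' @param min_overlap absolute overlap floor for a flag.
#' @return tibble: `channel_a`, `channel_b`, `pair_overlap`,
#'   `median_overlap_all`, `fold`, `flagged`.
#' @export
translocation_screen <- function(summary, fold_threshold = 1.5,
                                 min_overlap = 0.1) {
  stopifnot(inherits(summary, "ct_summary"))
  ch <- summary$channels
  prs <- utils::combn(ch, 2L, simplify = FALSE)
  if (length(prs) < 3L) {
    stop("need at least 3 channel pairs to define a background level", call. = FALSE)
  }
  pair_ov <- vapply(prs, function(pr) {
    mean(c(summary$overlap[pr[1], pr[2]], summary$overlap[pr[2], pr[1]]),
         na.rm = TRUE)
  }, 1)
  med_all <- median(pair_ov, na.rm = TRUE)
  tibble::tibble(
    channel_a = vapply(prs, `[`, "", 1L),
    channel_b = vapply(prs, `[`, "", 2L),
    pair_overlap = pair_ov,
    median_overlap_all = med_all,
    fold = pair_ov / med_all,
    flagged = pair_ov > fold_threshold * med_all & pair_ov >= min_overlap
  )
}
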