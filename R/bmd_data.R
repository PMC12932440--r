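#' Read cross-sectional BMD study tables
#'
#' Reads a CSV of per-study BMD summaries with the strict schema
#' `study_id, site, menopause_type, time_years, mean_bmd, sd, n`:
#' one row per (study, time point), `time_years` measured since
#' menopause onset, `mean_bmd` in g/cm^2 (or already normalized),
#' `sd` on the same scale, and `n` the number of women behind the
#' point. Validation errors report 1-based data line numbers.
#'
#' @param path CSV file path.
#' @return A list of `bmd_study` objects, one per unique
#'   `(study_id, site, menopause_type)` combination, each holding a
#'   `points` data frame.
#' @export
read_bmd_studies <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("study_id", "site", "menopause_type", "time_years",
                "mean_bmd", "sd", "n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  problems <- character(0)
  note <- function(i, msg) sprintf("line %d: %s", i + 1L, msg)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!r$menopause_type %in% c("natural", "surgical"))
      problems <- c(problems,
                    note(i, "menopause_type must be natural or surgical"))
    if (!is.finite(r$time_years))
      problems <- c(problems, note(i, "time_years must be finite"))
    if (!is.finite(r$mean_bmd) || r$mean_bmd <= 0)
      problems <- c(problems, note(i, "mean_bmd must be positive"))
    if (!is.finite(r$sd) || r$sd < 0)
      problems <- c(problems, note(i, "sd must be >= 0"))
    if (!is.finite(r$n) || r$n < 1)
      problems <- c(problems, note(i, "n must be >= 1"))
  }
  if (length(problems))
    stop("invalid BMD table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  key <- interaction(df$study_id, df$site, df$menopause_type, drop = TRUE)
  lapply(split(df, key), function(d) {
    bmd_study(study_id = d$study_id[1L], site = d$site[1L],
              menopause_type = d$menopause_type[1L],
              points = d[order(d$time_years),
                         c("time_years", "mean_bmd", "sd", "n")])
  })
}

#' Construct a single-study BMD dataset
#'
#' @param study_id,site Labels identifying the study and skeletal site.
#' @param menopause_type `"natural"` or `"surgical"`.
#' @param points Data frame with columns `time_years` (since onset),
#'   `mean_bmd`, `sd`, `n`.
#' @return A `bmd_study` object.
#' @export
bmd_study <- function(study_id, site = "lumbar_spine",
                      menopause_type = c("natural", "surgical"),
                      points) {
  menopause_type <- match.arg(menopause_type)
  stopifnot(is.data.frame(points),
            all(c("time_years", "mean_bmd", "sd", "n") %in%
                  names(points)))
  if (any(!is.finite(points$time_years)))
    stop("times must be finite", call. = FALSE)
  if (any(points$n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(points$sd < 0)) stop("sd must be >= 0", call. = FALSE)
  x <- list(study_id = study_id, site = site,
            menopause_type = menopause_type,
            points = points[order(points$time_years), , drop = FALSE])
  class(x) <- c("bmd_study", "list")
  x
}

#' Normalize a study to its BMD at menopause onset
#'
#' Divides every mean (and SD, preserving the coefficient of
#' variation) by the study's reference mean at onset: the observation
#' closest to `time = 0`, which must fall within `onset_window` years.
#' Times are already expressed relative to onset by the input schema.
#' The pipeline is idempotent: normalizing an already-normalized
#' series changes nothing, and uniform rescaling of the raw values
#' leaves the output unchanged.
#'
#' @param study A `bmd_study`.
#' @param onset_window Maximum |time| (years) for the reference
#'   observation (default 1).
#' @return A `bmd_series`: data frame with `time_years`,
#'   `mean_bmd` (normalized, 1 at the reference point), `sd`, `n`, and
#'   a `provenance` attribute naming the contributing study.
#' @export
normalize_study <- function(study, onset_window = 1) {
  stopifnot(inherits(study, "bmd_study"))
  pts <- study$points
  i_ref <- which.min(abs(pts$time_years))
  if (abs(pts$time_years[i_ref]) > onset_window)
    stop(sprintf(
      "study %s has no observation within %g years of menopause onset",
      study$study_id, onset_window), call. = FALSE)
  ref <- pts$mean_bmd[i_ref]
  out <- data.frame(time_years = pts$time_years,
                    mean_bmd = pts$mean_bmd / ref,
                    sd = pts$sd / ref,
                    n = pts$n)
  bmd_series(out, provenance = paste(study$study_id, study$site,
                                     sep = "/"))
}

#' Construct a normalized BMD observation series
#'
#' A `bmd_series` holds onset-normalized BMD observations: columns
#' `time_years` (since menopause onset), `mean_bmd` (dimensionless,
#' positive; 1 at the onset reference), `sd`, and `n` (cohort size),
#' with a `provenance` attribute naming the contributing studies.
#' Usually produced by [normalize_study()] or [aggregate_bmd()]; exposed
#' for users supplying series that are already normalized.
#'
#' @param df Data frame with the four columns above.
#' @param provenance Character vector of contributing study labels.
#' @return A `bmd_series` object (a data frame).
#' @export
bmd_series <- function(df, provenance = character(0)) {
  stopifnot(all(c("time_years", "mean_bmd", "sd", "n") %in% names(df)))
  if (any(df$mean_bmd <= 0))
    stop("normalized BMD values must be positive", call. = FALSE)
  df <- df[order(df$time_years), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  class(df) <- c("bmd_series", "data.frame")
  df
}

#' Aggregate normalized BMD series across studies
#'
#' Pools several onset-normalized series into one, binning
#' observations into `bin_width`-year windows. Within each bin the
#' default is the cohort-size-weighted pooled mean with a pooled SD
#' combining within-study and between-study variance (the grand
#' variance of the mixture); `weighted = FALSE` gives each study point
#' equal weight instead. Empty bins are dropped. Aggregation is
#' invariant to the order of the input series.
#'
#' @param series A list of `bmd_series` objects (at least one).
#' @param bin_width Bin width in years (default 1).
#' @param weighted Weight by cohort size `n` (default `TRUE`).
#' @return A pooled `bmd_series`; `n` is the total cohort size per bin
#'   and `provenance` the union of the inputs'.
#' @export
aggregate_bmd <- function(series, bin_width = 1, weighted = TRUE) {
  if (inherits(series, "bmd_series")) series <- list(series)
  if (length(series) < 1L) stop("need at least one series",
                                call. = FALSE)
  stopifnot(all(vapply(series, inherits, logical(1), "bmd_series")))
  all_pts <- do.call(rbind, lapply(series, as.data.frame))
  prov <- sort(unique(unlist(lapply(series, attr, "provenance"))))
  bin <- floor(all_pts$time_years / bin_width)
  pooled <- lapply(split(all_pts, bin), function(d) {
    w <- if (weighted) d$n else rep(1, nrow(d))
    N <- sum(w)
    m <- sum(w * d$mean_bmd) / N
    # grand variance: within + between components of the mixture
    v <- sum(w * (d$sd^2 + d$mean_bmd^2)) / N - m^2
    data.frame(time_years = sum(w * d$time_years) / N,
               mean_bmd = m,
               sd = sqrt(max(v, 0)),
               n = sum(d$n))
  })
  bmd_series(do.call(rbind, pooled), provenance = prov)
}

#' Illustrative linear bone-loss rate
#'
#' Ordinary least-squares slope of normalized BMD against years since
#' onset over `[0, window_years]`, reported in percent per year. This
#' mirrors the linear fits drawn through the first 15 post-menopausal
#' years of the aggregated data; it is a descriptive diagnostic only
#' and plays no role in the mechanistic model.
#'
#' @param series A `bmd_series`.
#' @param window_years Fitting window (default 15).
#' @return Slope in percent of the onset value per year (negative =
#'   loss).
#' @export
linear_loss_rate <- function(series, window_years = 15) {
  stopifnot(inherits(series, "bmd_series"))
  d <- series[series$time_years >= 0 &
                series$time_years <= window_years, ]
  if (nrow(d) < 2L)
    stop("need at least two observations inside the window",
         call. = FALSE)
  if (length(unique(d$time_years)) < 2L)
    stop("degenerate window: all observations at the same time",
         call. = FALSE)
  fit <- stats::lm(mean_bmd ~ time_years, data = d)
  unname(stats::coef(fit)[2L]) * 100
}

#' Write a normalized BMD series as CSV
#'
#' @param series A `bmd_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bmd_series_csv <- function(series, path) {
  stopifnot(inherits(series, "bmd_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
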