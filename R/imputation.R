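ds_feature_cols <- function(tbl) {
  grep("^ds[0-9]+$", names(tbl), value = TRUE)
}

milestone_feature_cols <- function(tbl) {
  intersect(c("ttfp_s", "t_half_s", "time_ratio", "upslope",
              ds_feature_cols(tbl), "kurtosis"), names(tbl))
}

#' K-nearest-neighbour imputation within a training feature table
#'
#' Fills missing downslope milestones by comparing each incomplete ROI to
#' the other ROIs *within the same (training) table*: features are
#' standardized to zero mean and unit variance, row-to-row distances are
#' Euclidean over the features observed in both rows (scaled by the number
#' of shared features), and each missing cell is replaced by the mean of
#' that column over the `k` nearest rows in which it is observed. Observed
#' cells are never altered.
#'
#' @param feature_table A feature table from [build_feature_table()].
#' @param k Number of neighbours.
#' @param feature_cols Columns used for distances and eligible for
#'   imputation (default: all milestone columns present).
#' @return A list with `table` (completed; `*_provenance` set to
#'   `"imputed"` for filled cells) and `log` (one row per imputed cell with
#'   the donor trace ids and the value).
#' @export
knn_impute_train <- function(feature_table, k = 5, feature_cols = NULL) {
  tbl <- feature_table
  if (is.null(feature_cols)) feature_cols <- milestone_feature_cols(tbl)
  X <- as.matrix(tbl[feature_cols])
  n <- nrow(X)
  if (k >= n)
    stop("k must be smaller than the number of rows", call. = FALSE)

  entirely_missing <- feature_cols[colSums(!is.na(X)) == 0]
  if (length(entirely_missing) > 0)
    stop(sprintf("column(s) entirely missing: %s",
                 paste(entirely_missing, collapse = ", ")), call. = FALSE)

  mu <- colMeans(X, na.rm = TRUE)
  sdv <- apply(X, 2, stats::sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  log_rows <- list()
  for (col in feature_cols) {
    miss_rows <- which(is.na(X[, col]))
    if (length(miss_rows) == 0) next
    donors_all <- which(!is.na(X[, col]))
    if (length(donors_all) < k)
      stop(sprintf("fewer than k = %d rows observe %s", k, col),
           call. = FALSE)
    for (r in miss_rows) {
      d <- vapply(donors_all, function(dr) {
        shared <- which(!is.na(Z[r, ]) & !is.na(Z[dr, ]))
        if (length(shared) == 0) return(Inf)
        sqrt(sum((Z[r, shared] - Z[dr, shared])^2) / length(shared))
      }, numeric(1))
      nearest <- donors_all[order(d)[seq_len(k)]]
      value <- mean(X[nearest, col])
      tbl[r, col] <- value
      prov_col <- paste0(col, "_provenance")
      if (prov_col %in% names(tbl)) tbl[r, prov_col] <- "imputed"
      log_rows[[length(log_rows) + 1]] <- data.frame(
        trace_id = tbl$trace_id[r], column = col,
        donors = paste(tbl$trace_id[nearest], collapse = ";"),
        value = value, stringsAsFactors = FALSE)
    }
  }
  log <- if (length(log_rows) > 0) do.call(rbind, log_rows) else
    data.frame(trace_id = character(), column = character(),
               donors = character(), value = numeric())
  list(table = tbl, log = log)
}

#' Fit an exponential model to a normalized post-peak tail
#'
#' Fits \eqn{F(\Delta t) = a e^{-b \Delta t} + c} (nonlinear least squares,
#' `b >= 0`) to post-peak normalized intensities, where \eqn{\Delta t} is
#' time since the peak. The offset `c` accommodates the non-washing plateau
#' of ICG-retaining (malignant) tissue; set `model = "pure"` for the
#' 2-parameter decay without offset. Initialization: `c0` = last observed
#' value, `a0 = 1 - c0`, `b0` from a log-linear regression on `F - c0`.
#'
#' @param dt_s Time since peak (seconds, >= 0).
#' @param values Normalized intensities at `dt_s`.
#' @param model `"offset"` (default) or `"pure"`.
#' @return An object of class `exponential_tail_fit`: list with `a`, `b`,
#'   `c`, `rmse`.
#' @export
fit_exponential_tail <- function(dt_s, values, model = c("offset", "pure")) {
  model <- match.arg(model)
  if (length(dt_s) < 5)
    stop("insufficient tail: need at least 5 post-peak samples",
         call. = FALSE)
  df <- data.frame(dt = dt_s, y = values)

  if (diff(range(values)) < 1e-12) {
    # constant tail: zero decay, offset = the constant
    return(structure(list(a = 0, b = 0, c = mean(values), rmse = 0),
                     class = "exponential_tail_fit"))
  }

  # separable least squares: for fixed b the model is linear in (a, c), so
  # profile b over a log grid, then polish the grid optimum with nlsLM.
  # Near-flat tails make a joint 3-parameter start ill-conditioned (a ~ 0
  # zeroes the b-gradient); the profile route has no such failure mode.
  b_grid <- c(0, exp(seq(log(1e-4), log(1), length.out = 60)))
  best <- NULL
  for (b in b_grid) {
    e <- exp(-b * dt_s)
    coefs <- tryCatch({
      if (model == "offset") {
        if (stats::sd(e) < 1e-12) c(0, mean(values))  # b ~ 0: constant model
        else stats::coef(stats::lm(values ~ e))[c(2, 1)]
      } else c(sum(values * e) / sum(e * e), 0)
    }, error = function(err) NULL)
    if (is.null(coefs) || anyNA(coefs)) next
    a <- max(unname(coefs[1]), 0)
    cc <- unname(coefs[2])
    sse <- sum((values - (a * e + cc))^2)
    if (is.null(best) || sse < best$sse)
      best <- list(a = a, b = b, c = cc, sse = sse)
  }
  if (is.null(best))
    stop("exponential tail fit did not converge (no admissible profile point)",
         call. = FALSE)

  # Levenberg-Marquardt polish via nls.lm: its damping tolerates the
  # near-collinear Jacobian of a slow exponential, which makes the nls
  # model interface reject such starts outright
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                     ptol = 1e-15)
  polished <- tryCatch({
    if (model == "offset")
      minpack.lm::nls.lm(
        par = c(a = max(best$a, 1e-6), b = best$b, c = best$c),
        fn = function(p) values - (p[1] * exp(-p[2] * dt_s) + p[3]),
        lower = c(0, 0, -0.5), upper = c(2, 1, 1.5), control = ctrl)
    else
      minpack.lm::nls.lm(
        par = c(a = max(best$a, 1e-6), b = best$b),
        fn = function(p) values - p[1] * exp(-p[2] * dt_s),
        lower = c(0, 0), upper = c(2, 1), control = ctrl)
  }, error = function(e) NULL)

  if (!is.null(polished) && polished$deviance <= best$sse + 1e-12) {
    p <- polished$par
    structure(list(a = unname(p["a"]), b = unname(p["b"]),
                   c = if (model == "offset") unname(p["c"]) else 0,
                   rmse = sqrt(polished$deviance / length(values))),
              class = "exponential_tail_fit")
  } else {
    structure(list(a = best$a, b = best$b, c = best$c,
                   rmse = sqrt(best$sse / length(values))),
              class = "exponential_tail_fit")
  }
}

#' @export
print.exponential_tail_fit <- function(x, ...) {
  cat(sprintf("<exponential_tail_fit> F(dt) = %.4f * exp(-%.5f dt) + %.4f  (rmse %.2e)\n",
              x$a, x$b, x$c, x$rmse))
  invisible(x)
}

#' Exponential-fit imputation for a single test trace
#'
#' Extrapolates missing downslope milestones of one trace from an
#' exponential fit to its observed post-peak tail. This is the test-time
#' counterpart of [knn_impute_train()]: a single video under inference has
#' no "neighbours" to borrow from, so its own tail kinetics are fitted and
#' extrapolated. The fitted downslope at horizon `N` is
#' \eqn{(a e^{-bN} + c - 1)/N}. No other trace's data is used.
#'
#' @param trace The smoothed, normalized trace the milestones came from.
#' @param milestones A `milestone_features` object for this trace, or a
#'   one-row slice of a feature table.
#' @param horizons_to_fill Horizons (seconds) to impute; default: all
#'   downslope fields currently missing.
#' @param model Tail model, see [fit_exponential_tail()].
#' @return The milestones with missing downslopes filled and their
#'   provenance set to `"imputed"`; the fit is attached as attribute
#'   `"tail_fit"`.
#' @export
exp_impute_test <- function(trace, milestones, horizons_to_fill = NULL,
                            model = "offset") {
  is_row <- is.data.frame(milestones)
  get_ds <- function(h) {
    if (is_row) milestones[[paste0("ds", h)]] else
      milestones[[paste0("ds", h)]]
  }
  all_h <- if (is_row)
    as.integer(sub("^ds", "", ds_feature_cols(milestones)))
  else
    as.integer(sub("^ds", "", names(milestones$provenance)))
  if (is.null(horizons_to_fill))
    horizons_to_fill <- all_h[vapply(all_h, function(h) is.na(get_ds(h)),
                                     logical(1))]
  if (length(horizons_to_fill) == 0) return(milestones)

  peak <- detect_first_peak(trace)
  post <- which(trace$time_s >= peak$time_s)
  fit <- fit_exponential_tail(trace$time_s[post] - peak$time_s,
                              trace$intensity[post], model = model)
  for (h in horizons_to_fill) {
    val <- (fit$a * exp(-fit$b * h) + fit$c - 1) / h
    if (is_row) {
      milestones[[paste0("ds", h)]] <- val
      prov_col <- paste0("ds", h, "_provenance")
      if (prov_col %in% names(milestones)) milestones[[prov_col]] <- "imputed"
    } else {
      milestones[[paste0("ds", h)]] <- val
      milestones$provenance[[paste0("ds", h)]] <- "imputed"
    }
  }
  attr(milestones, "tail_fit") <- fit
  milestones
}
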