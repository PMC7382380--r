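# Seed C:N stoichiometry: orthogonal (total-least-squares) regression of
# seed C% on N%, the signed delta-seed-composition (DSC) trait, stress
# shifts of the line, and genotype response vectors.

#' Orthogonal regression of seed C% on N%
#'
#' Fits the major axis: the line through the centroid along the leading
#' eigenvector of the 2x2 covariance of (N%, C%), which minimizes the sum of
#' squared perpendicular distances. Closed form for the slope when the
#' cross-product is nonzero:
#' b = (S_cc - S_nn + sqrt((S_cc - S_nn)^2 + 4 S_nc^2)) / (2 S_nc).
#' With `method = "rma"` the reduced-major-axis (geometric mean) slope
#' sign(S_nc) * sqrt(S_cc / S_nn) is used instead.
#'
#' @param n_pct,c_pct seed N% and C% coordinates (equal length, >= 3 points).
#' @param method `"ma"` (major axis, default) or `"rma"`.
#' @return object of class `stoich_fit`: `slope`, `intercept`, `centroid`
#'   (named c(n, c)), `n_points`, `rss_orth` (sum of squared orthogonal
#'   residuals), `method`. A horizontal major axis gives slope 0; a vertical
#'   one gives slope `Inf` with `NA` intercept and a flag.
#' @export
fit_orthogonal <- function(n_pct, c_pct, method = c("ma", "rma")) {
  method <- match.arg(method)
  stopifnot(length(n_pct) == length(c_pct))
  keep <- is.finite(n_pct) & is.finite(c_pct)
  n_pct <- n_pct[keep]; c_pct <- c_pct[keep]
  if (length(n_pct) < 3) stop("domain error: need at least 3 points")
  mn <- mean(n_pct); mc <- mean(c_pct)
  dn <- n_pct - mn; dc <- c_pct - mc
  s_nn <- sum(dn^2); s_cc <- sum(dc^2); s_nc <- sum(dn * dc)
  if (s_nn == 0 && s_cc == 0) stop("degenerate fit: all points identical")

  vertical <- FALSE
  if (method == "rma") {
    if (s_nn == 0 || s_cc == 0) stop("degenerate fit: RMA needs variance on both axes")
    if (s_nc == 0) stop("degenerate fit: zero correlation, RMA sign undefined")
    slope <- sign(s_nc) * sqrt(s_cc / s_nn)
  } else if (s_nc == 0) {
    if (s_nn == s_cc) {
      stop("degenerate fit: isotropic scatter, major-axis direction undefined")
    }
    if (s_nn > s_cc) slope <- 0 else { slope <- Inf; vertical <- TRUE }
  } else {
    slope <- (s_cc - s_nn + sqrt((s_cc - s_nn)^2 + 4 * s_nc^2)) / (2 * s_nc)
  }

  if (vertical) {
    intercept <- NA_real_
    rss <- sum(dn^2)
  } else {
    intercept <- mc - slope * mn
    rss <- sum((dc - slope * dn)^2) / (1 + slope^2)
  }
  structure(list(slope = slope, intercept = intercept,
                 centroid = c(n = mn, c = mc), n_points = length(n_pct),
                 rss_orth = rss, method = method, vertical = vertical),
            class = "stoich_fit")
}

#' @export
print.stoich_fit <- function(x, ...) {
  cat("<stoich_fit> C% = ", format(x$intercept, digits = 6), " + ",
      format(x$slope, digits = 6), " x N%  (", x$method, ", n = ",
      x$n_points, ", orthogonal RSS = ", format(x$rss_orth, digits = 6),
      ")\n", sep = "")
  invisible(x)
}

#' Signed delta seed composition (DSC) of points against a fitted line
#'
#' DSC is the signed orthogonal distance of a seed's (N%, C%) point from the
#' stoichiometry line: DiffC is the vertical gap at the point's N%, DiffN the
#' horizontal gap at the point's C%, and the magnitude is the altitude of the
#' right triangle they span, |DiffN x DiffC| / sqrt(DiffN^2 + DiffC^2),
#' which equals the Euclidean point-line distance. Points above the line
#' (positive DiffC) get positive DSC. For a negatively sloped line DiffN and
#' DiffC always share a sign; should they ever disagree (possible only for
#' positive slopes) the sign is taken from DiffC and the row is flagged.
#'
#' @param n_pct,c_pct point coordinates (vectorized).
#' @param fit a `stoich_fit` (or any list with `slope` and `intercept`).
#' @return data.frame with `diff_n`, `diff_c`, `dsc`, `flagged`.
#' @export
dsc <- function(n_pct, c_pct, fit) {
  b <- fit$slope; a <- fit$intercept
  if (!is.finite(b) || b == 0) {
    # horizontal/vertical line: only one gap is finite; distance direct
    if (is.finite(b)) {         # b == 0
      diff_c <- c_pct - a
      out <- data.frame(diff_n = NA_real_, diff_c = diff_c, dsc = diff_c,
                        flagged = TRUE)
    } else {                    # vertical through centroid
      diff_n <- n_pct - fit$centroid[["n"]]
      out <- data.frame(diff_n = diff_n, diff_c = NA_real_, dsc = diff_n,
                        flagged = TRUE)
    }
    return(out)
  }
  diff_c <- c_pct - (a + b * n_pct)
  diff_n <- n_pct - (c_pct - a) / b
  denom <- sqrt(diff_n^2 + diff_c^2)
  mag <- ifelse(denom == 0, 0, abs(diff_n * diff_c) / denom)
  val <- sign(diff_c) * mag
  data.frame(diff_n = diff_n, diff_c = diff_c, dsc = val,
             flagged = sign(diff_n) * sign(diff_c) < 0)
}

#' Fit the stoichiometry line within each design cell
#'
#' One orthogonal fit per group (default experiment x condition), pooling
#' all genotypes of the cell, plus the DSC of every seed against the line of
#' its own cell.
#'
#' @param seeds data.frame of seed rows: `n_pct`, `c_pct` and the grouping
#'   columns (a `nue_dataset` is accepted; its seed organ rows are used).
#' @param by grouping columns, default `c("experiment", "condition")`.
#' @param min_points cells with fewer points are skipped with a warning.
#' @param method passed to [fit_orthogonal()].
#' @return list with `fits` (data.frame: group labels, slope, intercept,
#'   centroid_n, centroid_c, n_points, rss_orth) and `dsc` (the seed rows
#'   with `diff_n`, `diff_c`, `dsc` appended).
#' @export
fit_seed_lines <- function(seeds, by = c("experiment", "condition"),
                           min_points = 3, method = "ma") {
  if (inherits(seeds, "nue_dataset")) {
    seeds <- seeds$records[seeds$records$organ == "seeds", ]
  }
  stopifnot(all(c("n_pct", "c_pct", by) %in% names(seeds)))
  key <- interaction(seeds[by], drop = TRUE, lex.order = TRUE)
  fit_rows <- list(); dsc_rows <- list()
  for (cell in split(seeds, key)) {
    if (nrow(cell) < min_points) {
      warning("cell ", paste(cell[1, by], collapse = "/"), " has ",
              nrow(cell), " seed point(s); skipped")
      next
    }
    fit <- fit_orthogonal(cell$n_pct, cell$c_pct, method = method)
    fit_rows[[length(fit_rows) + 1]] <- data.frame(
      cell[1, by, drop = FALSE], slope = fit$slope, intercept = fit$intercept,
      centroid_n = fit$centroid[["n"]], centroid_c = fit$centroid[["c"]],
      n_points = fit$n_points, rss_orth = fit$rss_orth, row.names = NULL)
    dsc_rows[[length(dsc_rows) + 1]] <- cbind(cell,
                                              dsc(cell$n_pct, cell$c_pct, fit))
  }
  if (length(fit_rows) == 0) stop("no cell had enough seed points to fit")
  fits <- do.call(rbind, fit_rows)
  dscs <- do.call(rbind, dsc_rows)
  rownames(fits) <- rownames(dscs) <- NULL
  list(fits = fits, dsc = dscs)
}

#' Stress-induced shifts of the stoichiometry line
#'
#' Within each experiment, the slope and intercept change of every stress
#' condition relative to that experiment's control fit; then the
#' across-experiment mean and SD per condition. Experiments without a
#' control fit are excluded with a warning.
#'
#' @param fits data.frame as returned in `fit_seed_lines()$fits`.
#' @param control label of the control condition, default `"control"`.
#' @return list with `per_experiment` (experiment, condition, d_slope,
#'   d_intercept) and `summary` (condition, n_experiments, mean_d_slope,
#'   sd_d_slope, mean_d_intercept, sd_d_intercept).
#' @export
condition_shifts <- function(fits, control = "control") {
  stopifnot(all(c("experiment", "condition", "slope", "intercept") %in% names(fits)))
  per_exp <- list()
  for (d in split(fits, fits$experiment)) {
    ctl <- d[d$condition == control, ]
    if (nrow(ctl) == 0) {
      warning("experiment ", d$experiment[1], " lacks a control fit; excluded")
      next
    }
    stress <- d[d$condition != control, ]
    if (nrow(stress) == 0) next
    per_exp[[length(per_exp) + 1]] <- data.frame(
      experiment = stress$experiment, condition = stress$condition,
      d_slope = stress$slope - ctl$slope[1],
      d_intercept = stress$intercept - ctl$intercept[1], row.names = NULL)
  }
  if (length(per_exp) == 0) {
    empty <- data.frame(experiment = character(0), condition = character(0),
                        d_slope = numeric(0), d_intercept = numeric(0))
    return(list(per_experiment = empty,
                summary = data.frame(condition = character(0),
                                     n_experiments = integer(0),
                                     mean_d_slope = numeric(0),
                                     sd_d_slope = numeric(0),
                                     mean_d_intercept = numeric(0),
                                     sd_d_intercept = numeric(0))))
  }
  per_exp <- do.call(rbind, per_exp)
  summ <- do.call(rbind, lapply(split(per_exp, per_exp$condition), function(d) {
    data.frame(condition = d$condition[1], n_experiments = nrow(d),
               mean_d_slope = mean(d$d_slope),
               sd_d_slope = if (nrow(d) > 1) stats::sd(d$d_slope) else NA_real_,
               mean_d_intercept = mean(d$d_intercept),
               sd_d_intercept = if (nrow(d) > 1) stats::sd(d$d_intercept) else NA_real_,
               row.names = NULL)
  }))
  rownames(summ) <- NULL
  list(per_experiment = per_exp, summary = summ)
}

#' Genotype response vectors of seed composition
#'
#' For each genotype, the displacement of its mean seed (N%, C%) under each
#' stress from its own control baseline: the vector (dN%, dC%), its length
#' and angle. Per condition, a homogeneity summary: mean vector length and
#' the circular SD of the angles; a condition is labelled heterogeneous when
#' the circular SD exceeds `heterogeneity_deg`.
#'
#' @param seeds data.frame of seed rows with `genotype`, `condition`,
#'   `n_pct`, `c_pct` (a `nue_dataset` is accepted).
#' @param control control condition label, default `"control"`.
#' @param heterogeneity_deg circular-SD threshold in degrees, default 60.
#' @return list with `vectors` (genotype, condition, d_n, d_c, length,
#'   angle_deg — `NA` angle for a zero vector) and `summary` (condition,
#'   n_genotypes, mean_length, circ_sd_deg, heterogeneous).
#' @export
response_vectors <- function(seeds, control = "control",
                             heterogeneity_deg = 60) {
  if (inherits(seeds, "nue_dataset")) {
    seeds <- seeds$records[seeds$records$organ == "seeds", ]
  }
  stopifnot(all(c("genotype", "condition", "n_pct", "c_pct") %in% names(seeds)))
  means <- stats::aggregate(cbind(n_pct, c_pct) ~ genotype + condition,
                            data = seeds, FUN = mean)
  ctl <- means[means$condition == control, ]
  rows <- list()
  for (g in unique(means$genotype)) {
    base <- ctl[ctl$genotype == g, ]
    if (nrow(base) == 0) {
      warning("genotype ", g, " has no control cell; skipped")
      next
    }
    stress <- means[means$genotype == g & means$condition != control, ]
    if (nrow(stress) == 0) next
    d_n <- stress$n_pct - base$n_pct
    d_c <- stress$c_pct - base$c_pct
    len <- sqrt(d_n^2 + d_c^2)
    ang <- ifelse(len == 0, NA_real_, atan2(d_c, d_n) * 180 / pi)
    rows[[length(rows) + 1]] <- data.frame(
      genotype = g, condition = stress$condition, d_n = d_n, d_c = d_c,
      length = len, angle_deg = ang, row.names = NULL)
  }
  if (length(rows) == 0) stop("no genotype has both control and stress cells")
  vectors <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(vectors, vectors$condition), function(d) {
    ang <- d$angle_deg[!is.na(d$angle_deg)] * pi / 180
    csd <- if (length(ang) > 0) {
      rbar <- sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
      sqrt(pmax(0, -2 * log(rbar))) * 180 / pi
    } else NA_real_
    data.frame(condition = d$condition[1], n_genotypes = nrow(d),
               mean_length = mean(d$length), circ_sd_deg = csd,
               heterogeneous = !is.na(csd) && csd > heterogeneity_deg,
               row.names = NULL)
  }))
  rownames(summ) <- NULL
  list(vectors = vectors, summary = summ)
}
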