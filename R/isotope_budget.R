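# Per-plant 15N/N mass balance and the derived efficiency indices.
#
# All indices are computed per plant and only then averaged ("means of
# ratios"): a genotype-by-condition mean of NUE is the mean of per-plant
# NHI/HI ratios, not the ratio of means.

#' 15N enrichment above natural abundance
#'
#' E% = A%_sample - A%_control. Slightly negative values are legitimate
#' measurement noise on unlabelled tissue and are kept unless `clamp = TRUE`.
#'
#' @param a15_sample sample atom percent, in \[0, 100\].
#' @param a15_control natural-abundance atom percent, in \[0, 100\].
#' @param clamp floor the result at zero (default `FALSE`).
#' @return enrichment in atom-percent points; vectorized.
#' @export
enrichment <- function(a15_sample, a15_control, clamp = FALSE) {
  stopifnot(all(a15_sample >= 0 & a15_sample <= 100, na.rm = TRUE),
            all(a15_control >= 0 & a15_control <= 100, na.rm = TRUE))
  e <- a15_sample - a15_control
  if (clamp) e <- pmax(e, 0)
  e
}

#' Nitrogen and tracer pools of a sample
#'
#' QtyN = DW x N%/100 (mg) and Qty15N = DW x E%/100 x N%/100 (mg of excess
#' 15N). Percentages are treated as true fractions so the pools are masses.
#'
#' @param dw_mg dry weight, mg, >= 0.
#' @param n_pct N concentration, mg per 100 mg DW.
#' @param e_pct enrichment in atom-percent points (see [enrichment()]).
#' @return data.frame with `qty_n_mg` and `qty_15n_mg`; vectorized.
#' @export
n_pools <- function(dw_mg, n_pct, e_pct) {
  if (any(dw_mg < 0, na.rm = TRUE)) stop("domain error: dw_mg must be >= 0")
  data.frame(qty_n_mg = dw_mg * n_pct / 100,
             qty_15n_mg = dw_mg * (e_pct / 100) * (n_pct / 100))
}

#' Per-plant mass-balance indices
#'
#' For every plant with all three organs present, computes organ N and 15N
#' pools, allocation fractions, and the efficiency indices:
#' HI = DW_seeds / DW_total, NHI = N allocation to seeds, 15NHI = 15N
#' allocation to seeds, NUtE = total DW / total QtyN (mg DW per mg N),
#' NUE = NHI / HI, NRE = 15NHI / HI.
#'
#' Plants with seed DW below `guard_dw_mg` are flagged degenerate: `nue` and
#' `nre` are `NaN` (their HI denominator is no longer a meaningful sink
#' size), while HI, allocations, NHI and NUtE are still reported. Negative
#' enrichment is tolerated but tracer pools are floored at zero before
#' forming allocation fractions, so fractions stay in \[0, 1\].
#'
#' @param dataset a [nue_dataset()].
#' @param guard_dw_mg seed dry-weight guard below which ratio indices are
#'   `NaN`, default 1 mg.
#' @param clamp_enrichment passed to [enrichment()] as `clamp`.
#' @return data.frame, one row per complete plant: design labels, per-organ
#'   `dw_*`, `e_pct_*`, `qty_n_*`, `qty_15n_*`, allocation fractions
#'   `alloc_n_*` / `alloc_15n_*`, `hi`, `nhi`, `nhi15`, `nute`, `nue`,
#'   `nre`, `degenerate`. Plants missing an organ are skipped with a warning.
#' @export
plant_indices <- function(dataset, guard_dw_mg = 1, clamp_enrichment = FALSE) {
  stopifnot(inherits(dataset, "nue_dataset"))
  rec <- dataset$records
  split_rec <- split(rec, rec$plant_id)
  complete <- vapply(split_rec, function(d) all(ORGANS %in% d$organ), logical(1))
  if (any(!complete)) {
    warning(sum(!complete), " plant(s) without all three organs skipped: ",
            paste(utils::head(names(split_rec)[!complete], 5), collapse = ", "))
  }
  split_rec <- split_rec[complete]
  if (length(split_rec) == 0) stop("no plant has all three organs")

  rows <- lapply(split_rec, function(d) {
    d <- d[match(ORGANS, d$organ), ]
    dw <- d$dw_mg
    total_dw <- sum(dw)
    if (total_dw == 0) stop("domain error: total aboveground DW is 0 for plant ",
                            d$plant_id[1])
    e <- enrichment(d$a15_pct, dataset$a15_control_pct,
                    clamp = clamp_enrichment)
    pools <- n_pools(dw, d$n_pct, e)
    qn <- pools$qty_n_mg
    q15 <- pools$qty_15n_mg
    q15_floor <- pmax(q15, 0)

    total_n <- sum(qn)
    total_15n <- sum(q15_floor)
    alloc_n <- if (total_n > 0) qn / total_n else rep(NaN, 3)
    alloc_15n <- if (!anyNA(total_15n) && isTRUE(total_15n > 0)) {
      q15_floor / total_15n
    } else rep(NaN, 3)

    hi <- dw[3] / total_dw
    nhi <- alloc_n[3]
    nhi15 <- alloc_15n[3]
    nute <- if (total_n > 0) total_dw / total_n else NaN
    degenerate <- dw[3] < guard_dw_mg
    nue <- if (degenerate) NaN else nhi / hi
    nre <- if (degenerate) NaN else nhi15 / hi

    data.frame(plant_id = d$plant_id[1], genotype = d$genotype[1],
               condition = d$condition[1], experiment = d$experiment[1],
               dw_rosette = dw[1], dw_stem = dw[2], dw_seeds = dw[3],
               e_pct_rosette = e[1], e_pct_stem = e[2], e_pct_seeds = e[3],
               qty_n_rosette = qn[1], qty_n_stem = qn[2], qty_n_seeds = qn[3],
               qty_15n_rosette = q15[1], qty_15n_stem = q15[2],
               qty_15n_seeds = q15[3],
               alloc_n_rosette = alloc_n[1], alloc_n_stem = alloc_n[2],
               alloc_n_seeds = alloc_n[3],
               alloc_15n_rosette = alloc_15n[1], alloc_15n_stem = alloc_15n[2],
               alloc_15n_seeds = alloc_15n[3],
               hi = hi, nhi = nhi, nhi15 = nhi15, nute = nute,
               nue = nue, nre = nre, degenerate = degenerate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

RATIO_INDICES <- c("nue", "nre")
INDEX_COLUMNS <- c("hi", "nhi", "nhi15", "nute", "nue", "nre",
                   "alloc_n_rosette", "alloc_n_stem", "alloc_n_seeds",
                   "alloc_15n_rosette", "alloc_15n_stem", "alloc_15n_seeds")

#' Mean and standard error of indices per design cell
#'
#' Arithmetic mean and SE of each per-plant index, grouped by condition or
#' condition x genotype. Degenerate plants are excluded from the ratio
#' indices (`nue`, `nre`) and counted separately; an empty cell is reported
#' as missing, never as zero. SE is `NA` for a single plant.
#'
#' @param indices table from [plant_indices()].
#' @param by grouping columns, default `"condition"`; use
#'   `c("condition", "genotype")` for the factorial summary.
#' @param index_cols indices to summarise, default all of them.
#' @return long data.frame: grouping columns, `index`, `n`, `mean`, `se`,
#'   `n_degenerate`.
#' @export
condition_summary <- function(indices, by = "condition",
                              index_cols = INDEX_COLUMNS) {
  stopifnot(all(by %in% names(indices)), all(index_cols %in% names(indices)))
  key <- interaction(indices[by], drop = TRUE, lex.order = TRUE)
  cells <- split(indices, key)
  out <- lapply(cells, function(cell) {
    labels <- cell[1, by, drop = FALSE]
    per_index <- lapply(index_cols, function(col) {
      vals <- cell[[col]]
      if (col %in% RATIO_INDICES) vals <- vals[!cell$degenerate]
      vals <- vals[is.finite(vals)]
      n <- length(vals)
      data.frame(labels, index = col, n = n,
                 mean = if (n > 0) mean(vals) else NA_real_,
                 se = if (n > 1) stats::sd(vals) / sqrt(n) else NA_real_,
                 n_degenerate = sum(cell$degenerate),
                 row.names = NULL)
    })
    do.call(rbind, per_index)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
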