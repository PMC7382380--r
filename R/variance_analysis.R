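# Three-way variance decomposition (genotype x condition x experiment),
# method-of-moments variance components from expected mean squares, the
# broad-sense heritability plug-in, and contrasts of each stress against
# control via estimated marginal means.

#' Three-way ANOVA decomposition and variance components
#'
#' Partitions a trait's sum of squares over the three main effects, the
#' three two-way interactions, the three-way interaction and the residual
#' (`stats::aov`; on balanced data all SS types coincide), and reports each
#' term's share of the total ("variance explained"). Variance components for
#' the genotype-related terms are then solved by method of moments from the
#' expected mean squares of the balanced random-effects layout with `r`
#' replicates per cell, `a` genotypes, `b` conditions, `c` experiments:
#' \preformatted{
#'   sigma2_err   = MS_res
#'   sigma2_gxcxe = (MS_GxCxE - MS_res) / r
#'   sigma2_gxc   = (MS_GxC - MS_GxCxE) / (r c)
#'   sigma2_gxe   = (MS_GxE - MS_GxCxE) / (r b)
#'   sigma2_cxe   = (MS_CxE - MS_GxCxE) / (r a)
#'   sigma2_gen   = (MS_G - MS_GxC - MS_GxE + MS_GxCxE) / (r b c)
#' }
#' Negative solutions are truncated to zero. On unbalanced data `r` is the
#' mean cell count and the components are flagged approximate.
#'
#' @param table data.frame with the trait column and `genotype`,
#'   `condition`, `experiment` labels.
#' @param trait name of the trait column.
#' @return object of class `variance_components`: the six components,
#'   `n_exp`, `k_cond`, `n_gen`, `r_reps`, `balanced`, `h2` (default
#'   divisor convention, see [heritability()]), `proportions` (data.frame
#'   term / df / ss / proportion) and `mean_squares`.
#' @export
anova_components <- function(table, trait) {
  stopifnot(is.data.frame(table), trait %in% names(table),
            all(c("genotype", "condition", "experiment") %in% names(table)))
  d <- data.frame(y = table[[trait]],
                  G = factor(table$genotype),
                  C = factor(table$condition),
                  E = factor(table$experiment))
  d <- d[is.finite(d$y), , drop = FALSE]
  d[] <- lapply(d, function(x) if (is.factor(x)) droplevels(x) else x)
  for (f in c("G", "C", "E")) {
    if (nlevels(d[[f]]) < 2) {
      stop("factor '", c(G = "genotype", C = "condition", E = "experiment")[f],
           "' has fewer than 2 levels")
    }
  }
  a <- nlevels(d$G); b <- nlevels(d$C); n_exp <- nlevels(d$E)
  cell_n <- table(d$G, d$C, d$E)
  balanced <- length(unique(as.vector(cell_n))) == 1 && all(cell_n > 0)
  r <- mean(cell_n)
  if (!balanced) {
    warning("unbalanced design: method-of-moments components are approximate")
  }

  constant <- stats::var(d$y) == 0 || is.na(stats::var(d$y))
  terms <- c("G", "C", "E", "G:C", "G:E", "C:E", "G:C:E", "Residuals")
  if (constant) {
    ss <- stats::setNames(rep(0, length(terms)), terms)
    ms <- ss
    df <- ss
    props <- rep(0, length(terms))
  } else {
    fit <- stats::aov(y ~ G * C * E, data = d)
    tab <- summary(fit)[[1]]
    lab <- trimws(rownames(tab))
    ss <- stats::setNames(tab[["Sum Sq"]][match(terms, lab)], terms)
    ss[is.na(ss)] <- 0
    df <- stats::setNames(tab[["Df"]][match(terms, lab)], terms)
    df[is.na(df)] <- 0
    ms <- ifelse(df > 0, ss / df, 0)
    props <- ss / sum(ss)
  }

  comp <- c(
    sigma2_err   = ms[["Residuals"]],
    sigma2_gxcxe = (ms[["G:C:E"]] - ms[["Residuals"]]) / r,
    sigma2_gxc   = (ms[["G:C"]] - ms[["G:C:E"]]) / (r * n_exp),
    sigma2_gxe   = (ms[["G:E"]] - ms[["G:C:E"]]) / (r * b),
    sigma2_cxe   = (ms[["C:E"]] - ms[["G:C:E"]]) / (r * a),
    sigma2_gen   = (ms[["G"]] - ms[["G:C"]] - ms[["G:E"]] + ms[["G:C:E"]]) /
                   (r * b * n_exp))
  comp <- pmax(comp, 0)

  vc <- structure(list(
    sigma2_gen = comp[["sigma2_gen"]], sigma2_gxc = comp[["sigma2_gxc"]],
    sigma2_gxe = comp[["sigma2_gxe"]], sigma2_cxe = comp[["sigma2_cxe"]],
    sigma2_gxcxe = comp[["sigma2_gxcxe"]], sigma2_err = comp[["sigma2_err"]],
    n_exp = n_exp, k_cond = b, n_gen = a, r_reps = r,
    balanced = balanced, constant = constant,
    proportions = data.frame(term = terms, df = as.numeric(df),
                             ss = as.numeric(ss),
                             proportion = as.numeric(props)),
    mean_squares = ms), class = "variance_components")
  vc$h2 <- heritability(vc)
  vc
}

#' Broad-sense heritability from variance components
#'
#' Plug-in from expected mean squares:
#' h2 = sG / (sG + sGxC/n + sGxE/k + sCxE/(n k) + sGxCxE/(n k) + sE/(n k)),
#' with n the number of experiments and k the number of conditions
#' (`divisor_convention = "swapped"`, the default). The `"conventional"`
#' switch instead divides each interaction by the number of levels of the
#' non-genotype factor(s) crossed into it: sGxC/k, sGxE/n, the rest as
#' above.
#'
#' @param vc a `variance_components` object, or a named list/vector with
#'   `sigma2_gen`, `sigma2_gxc`, `sigma2_gxe`, `sigma2_cxe`,
#'   `sigma2_gxcxe`, `sigma2_err`.
#' @param n_exp,k_cond design sizes; taken from `vc` when absent.
#' @param divisor_convention `"swapped"` or `"conventional"`.
#' @return h2 in \[0, 1\]; `NA` when every component is zero.
#' @export
heritability <- function(vc, n_exp = NULL, k_cond = NULL,
                         divisor_convention = c("swapped", "conventional")) {
  divisor_convention <- match.arg(divisor_convention)
  g <- function(nm) {
    v <- vc[[nm]]
    if (is.null(v)) stop("component '", nm, "' missing")
    v
  }
  n <- if (!is.null(n_exp)) n_exp else g("n_exp")
  k <- if (!is.null(k_cond)) k_cond else g("k_cond")
  s_gen <- g("sigma2_gen"); s_gxc <- g("sigma2_gxc"); s_gxe <- g("sigma2_gxe")
  s_cxe <- g("sigma2_cxe"); s_gce <- g("sigma2_gxcxe"); s_err <- g("sigma2_err")
  if (divisor_convention == "swapped") {
    den <- s_gen + s_gxc / n + s_gxe / k + s_cxe / (n * k) +
      s_gce / (n * k) + s_err / (n * k)
  } else {
    den <- s_gen + s_gxc / k + s_gxe / n + s_cxe / (n * k) +
      s_gce / (n * k) + s_err / (n * k)
  }
  if (den == 0) return(NA_real_)
  s_gen / den
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components>  (", x$n_gen, " genotypes x ", x$k_cond,
      " conditions x ", x$n_exp, " experiments, r = ",
      format(x$r_reps, digits = 4),
      if (!x$balanced) ", UNBALANCED: approximate" else "", ")\n", sep = "")
  comps <- c(gen = x$sigma2_gen, gxc = x$sigma2_gxc, gxe = x$sigma2_gxe,
             cxe = x$sigma2_cxe, gxcxe = x$sigma2_gxcxe, err = x$sigma2_err)
  print(round(comps, 6))
  cat("h2 =", format(x$h2, digits = 4), "\n")
  invisible(x)
}

#' Contrast of each stress condition against control
#'
#' Marginal (cell-balanced) mean difference stress - control from a linear
#' model with genotype and experiment as additive blocking factors, tested
#' two-sided via estimated marginal means. No multiplicity adjustment is
#' applied (flagged in the output attribute `adjust`).
#'
#' @param table data.frame with the trait column and design labels.
#' @param trait trait column name.
#' @param control control condition label, default `"control"`.
#' @return data.frame: `condition`, `estimate`, `se`, `df`, `t`, `p_value`;
#'   attribute `adjust = "none"`.
#' @export
contrast_vs_control <- function(table, trait, control = "control") {
  stopifnot(is.data.frame(table), trait %in% names(table),
            "condition" %in% names(table))
  d <- data.frame(y = table[[trait]], condition = factor(table$condition))
  for (blk in c("genotype", "experiment")) {
    if (blk %in% names(table)) d[[blk]] <- factor(table[[blk]])
  }
  d <- d[is.finite(d$y), , drop = FALSE]
  d[] <- lapply(d, function(x) if (is.factor(x)) droplevels(x) else x)
  if (!control %in% levels(d$condition)) stop("no control data present")
  if (nlevels(d$condition) < 2) stop("need at least one non-control condition")
  blocks <- intersect(c("genotype", "experiment"), names(d))
  blocks <- blocks[vapply(blocks, function(b) nlevels(d[[b]]) > 1, logical(1))]
  form <- stats::reformulate(c("condition", blocks), response = "y")
  fit <- stats::lm(form, data = d)
  em <- emmeans::emmeans(fit, specs = "condition")
  ctr <- emmeans::contrast(em, method = "trt.vs.ctrl",
                           ref = control, adjust = "none")
  s <- as.data.frame(summary(ctr))
  out <- data.frame(
    condition = sub(" - .*$", "", s$contrast),
    estimate = s$estimate, se = s$SE, df = s$df,
    t = s$t.ratio, p_value = s$p.value, row.names = NULL)
  attr(out, "adjust") <- "none"
  out
}

#' Heritability and variance-explained report across traits
#'
#' Runs [anova_components()] + [heritability()] for each requested trait
#' column and stacks the variance-explained proportions (the per-term share
#' of total SS) alongside h2.
#'
#' @param table data.frame with trait columns and design labels.
#' @param traits character vector of trait column names.
#' @param divisor_convention passed to [heritability()].
#' @return list with `h2` (data.frame trait / h2 / the six components /
#'   n_exp / k_cond) and `proportions` (long data.frame trait / term /
#'   proportion).
#' @export
heritability_report <- function(table, traits,
                                divisor_convention = "swapped") {
  stopifnot(all(traits %in% names(table)))
  h2_rows <- list(); prop_rows <- list()
  for (tr in traits) {
    vc <- anova_components(table, tr)
    h2_rows[[tr]] <- data.frame(
      trait = tr,
      h2 = heritability(vc, divisor_convention = divisor_convention),
      sigma2_gen = vc$sigma2_gen, sigma2_gxc = vc$sigma2_gxc,
      sigma2_gxe = vc$sigma2_gxe, sigma2_cxe = vc$sigma2_cxe,
      sigma2_gxcxe = vc$sigma2_gxcxe, sigma2_err = vc$sigma2_err,
      n_exp = vc$n_exp, k_cond = vc$k_cond, balanced = vc$balanced,
      row.names = NULL)
    prop_rows[[tr]] <- data.frame(trait = tr, vc$proportions[c("term", "proportion")],
                                  row.names = NULL)
  }
  list(h2 = do.call(rbind, c(h2_rows, make.row.names = FALSE)),
       proportions = do.call(rbind, c(prop_rows, make.row.names = FALSE)))
}
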