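# Factorial synthetic-data generator with known ground truth.
#
# Emulates the study design this package targets: 8 genotypes x 6
# post-flowering conditions x several experiments x 3-4 replicate plants,
# three organs per plant. Organ dry weights are log-normal around
# genotype/condition/experiment cell means; seed (N%, C%) points sit on a
# condition- and experiment-specific stoichiometry line and are displaced
# orthogonally by a genotype-persistent DSC offset plus noise; the 15N
# label dose is allocated across organs by condition-specific
# remobilization fractions and atom percents are back-computed, so the
# mass-balance module recovers those fractions exactly by construction.

.default_conditions <- c("control", "drought", "lowN", "defense", "dark", "heat")
.default_genotypes <- c("7", "63", "83", "134", "359", "397", "401", "442")

.cond_matrix <- function(rows, organs = ORGANS) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(.default_conditions, organs)
  m
}

#' Configuration of the synthetic factorial experiment
#'
#' Defaults emulate the reference design: 8 genotypes, the 6 post-flowering
#' conditions, 4 experiments, 4 plants per cell; control organ dry weights
#' 230/1590/840 mg (rosette/stem/seeds), control N allocation 7/53/40%,
#' control 15N allocation 9/40/51%, a seed stoichiometry line with slope
#' -4.0 and intercept 70.7, genotype DSC offsets spanning +/-0.5, and a
#' near-sterile heat condition (seed DW multiplier 0.024) that stress-tests
#' the degenerate-input guard while keeping ~95% of N trapped in the stem.
#'
#' @param genotypes,conditions,n_experiments,reps design sizes.
#' @param a15_control_pct natural-abundance atom percent.
#' @param label_dose_mg excess 15N applied per plant, mg.
#' @param dw_base_mg named control-organ dry-weight means, mg.
#' @param dw_condition_mult condition x organ dry-weight multipliers.
#' @param dw_sd_log log-scale SDs of the dry-weight effect layers
#'   (genotype, gxc, gxe, cxe, gxcxe, residual).
#' @param alloc_n_target,alloc_15n_target condition x organ allocation
#'   fraction targets (rows sum to 1).
#' @param alloc_n_noise_sd,alloc_15n_noise_sd log-scale SD of the per-plant
#'   multiplicative perturbation of the allocation targets (renormalized
#'   after perturbation).
#' @param stoich_slope,stoich_intercept control stoichiometry line.
#' @param stoich_condition_shift condition x (d_slope, d_intercept) shifts.
#' @param exp_slope_sd,exp_intercept_sd SD of per-experiment line wobble.
#' @param seed_n_genotype named genotype baseline seed N% (control).
#' @param seed_n_condition_shift named per-condition shift of seed N%.
#' @param seed_n_sd SDs of the seed-N% effect layers (exp, gxc, gxe, cxe,
#'   gxcxe, residual).
#' @param dsc_offsets named genotype-persistent orthogonal offsets.
#' @param dsc_sd SDs of the DSC noise layers (gxc, gxe, residual).
#' @param other_c_pct,other_c_sd rosette/stem C% mean and SD.
#' @param noise_scale single multiplier applied to every noise SD; 0 gives
#'   a noise-free dataset whose indices equal the configured targets
#'   exactly.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    genotypes = .default_genotypes,
    conditions = .default_conditions,
    n_experiments = 4,
    reps = 4,
    a15_control_pct = 0.3660,
    label_dose_mg = 0.015,
    dw_base_mg = c(rosette = 230, stem = 1590, seeds = 840),
    dw_condition_mult = .cond_matrix(list(
      control = c(1.00, 1.00, 1.00),
      drought = c(1.00, 0.70, 0.70),
      lowN    = c(0.45, 0.35, 0.45),
      defense = c(0.80, 1.00, 1.00),
      dark    = c(0.75, 0.80, 0.80),
      heat    = c(0.75, 0.80, 0.024))),
    dw_sd_log = list(genotype = 0.15, gxc = 0.05, gxe = 0.05,
                     cxe = 0.05, gxcxe = 0.05, residual = 0.15),
    alloc_n_target = .cond_matrix(list(
      control = c(0.07, 0.53, 0.40),
      drought = c(0.12, 0.37, 0.51),
      lowN    = c(0.04, 0.42, 0.54),
      defense = c(0.07, 0.51, 0.42),
      dark    = c(0.07, 0.48, 0.45),
      heat    = c(0.01, 0.95, 0.04))),
    alloc_n_noise_sd = 0.05,
    alloc_15n_target = .cond_matrix(list(
      control = c(0.09, 0.40, 0.51),
      drought = c(0.12, 0.28, 0.60),
      lowN    = c(0.06, 0.30, 0.64),
      defense = c(0.09, 0.33, 0.58),
      dark    = c(0.09, 0.32, 0.59),
      heat    = c(0.13, 0.82, 0.05))),
    alloc_15n_noise_sd = 0.05,
    stoich_slope = -4.0,
    stoich_intercept = 70.7,
    stoich_condition_shift = {
      m <- rbind(control = c(0, 0), drought = c(0, 0),
                 lowN = c(-0.5, -2.0), defense = c(0.4, 1.6),
                 dark = c(-0.4, -1.6), heat = c(0.5, 2.0))
      colnames(m) <- c("d_slope", "d_intercept"); m
    },
    exp_slope_sd = 0.35,
    exp_intercept_sd = 1.4,
    # baseline N% deliberately ~uncorrelated with dsc_offsets: the position
    # along the line and the orthogonal offset are independent genotype axes
    seed_n_genotype = stats::setNames(
      c(3.80, 4.12, 4.20, 3.80, 4.25, 3.87, 4.05, 4.12), .default_genotypes),
    seed_n_condition_shift = c(control = 0, drought = 0.4, lowN = -0.6,
                               defense = -0.3, dark = 0.1, heat = 0.8),
    seed_n_sd = list(exp = 0.15, gxc = 0.30, gxe = 0.20, cxe = 0.10,
                     gxcxe = 0.10, residual = 0.25),
    dsc_offsets = stats::setNames(
      c(0.05, 0.50, 0.30, -0.05, 0.00, 0.40, -0.45, -0.35),
      .default_genotypes),
    dsc_sd = list(gxc = 0.05, gxe = 0.05, residual = 0.15),
    other_c_pct = 42,
    other_c_sd = 1.0,
    noise_scale = 1) {
  cfg <- mget(names(formals(synthetic_config)), envir = environment())
  stopifnot(length(cfg$genotypes) >= 1, length(cfg$conditions) >= 1,
            cfg$n_experiments >= 1, cfg$reps >= 1,
            all(cfg$dw_base_mg >= 0), all(cfg$dw_condition_mult >= 0),
            all(cfg$alloc_n_target >= 0), all(cfg$alloc_15n_target >= 0),
            all(abs(rowSums(cfg$alloc_n_target) - 1) < 1e-9),
            all(abs(rowSums(cfg$alloc_15n_target) - 1) < 1e-9),
            all(unlist(cfg$dw_sd_log) >= 0), all(unlist(cfg$seed_n_sd) >= 0),
            all(unlist(cfg$dsc_sd) >= 0), cfg$noise_scale >= 0,
            all(cfg$conditions %in% rownames(cfg$dw_condition_mult)),
            all(cfg$conditions %in% rownames(cfg$alloc_n_target)),
            all(cfg$conditions %in% rownames(cfg$alloc_15n_target)),
            all(cfg$conditions %in% rownames(cfg$stoich_condition_shift)),
            all(cfg$conditions %in% names(cfg$seed_n_condition_shift)),
            all(cfg$genotypes %in% names(cfg$seed_n_genotype)),
            all(cfg$genotypes %in% names(cfg$dsc_offsets)))
  structure(cfg, class = "synthetic_config")
}

# effect table helper: array of iid normals, or zeros when sd == 0
.draw <- function(sd, dims) {
  array(stats::rnorm(prod(dims), sd = sd), dim = dims)
}

#' Simulate a factorial plant-organ dataset with ground truth
#'
#' See [synthetic_config()] for the generative model. Every latent quantity
#' (per-plant allocation fractions, the per-cell stoichiometry line, the
#' true orthogonal displacement of every seed point) is returned alongside
#' the dataset so recovery can be tested sharply.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed; identical config + seed give bit-identical output.
#' @return list with `dataset` (a [nue_dataset()]) and `truth`: `plants`
#'   (per-plant true allocation fractions, seed-line position, true DSC,
#'   line parameters), `lines` (per experiment x condition slope/intercept),
#'   and `config`.
#' @export
simulate_dataset <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  gs <- config$genotypes; cs <- config$conditions
  es <- as.character(seq_len(config$n_experiments))
  ng <- length(gs); nc <- length(cs); ne <- length(es)
  ns <- config$noise_scale

  # dry-weight effect layers, per organ (log scale)
  sdw <- lapply(config$dw_sd_log, function(s) s * ns)
  dw_g <- .draw(sdw$genotype, c(ng, 3))
  dw_gc <- .draw(sdw$gxc, c(ng, nc, 3))
  dw_ge <- .draw(sdw$gxe, c(ng, ne, 3))
  dw_ce <- .draw(sdw$cxe, c(nc, ne, 3))
  dw_gce <- .draw(sdw$gxcxe, c(ng, nc, ne, 3))

  # seed N% effect layers
  sn <- lapply(config$seed_n_sd, function(s) s * ns)
  n_e <- .draw(sn$exp, ne)
  n_gc <- .draw(sn$gxc, c(ng, nc))
  n_ge <- .draw(sn$gxe, c(ng, ne))
  n_ce <- .draw(sn$cxe, c(nc, ne))
  n_gce <- .draw(sn$gxcxe, c(ng, nc, ne))

  # DSC effect layers
  sd_d <- lapply(config$dsc_sd, function(s) s * ns)
  d_gc <- .draw(sd_d$gxc, c(ng, nc))
  d_ge <- .draw(sd_d$gxe, c(ng, ne))

  # per-experiment wobble of the stoichiometry line
  exp_slope <- .draw(config$exp_slope_sd * ns, ne)
  exp_int <- .draw(config$exp_intercept_sd * ns, ne)

  lines <- expand.grid(experiment = es, condition = cs,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lines$slope <- config$stoich_slope +
    config$stoich_condition_shift[lines$condition, "d_slope"] +
    exp_slope[as.integer(lines$experiment)]
  lines$intercept <- config$stoich_intercept +
    config$stoich_condition_shift[lines$condition, "d_intercept"] +
    exp_int[as.integer(lines$experiment)]

  design <- expand.grid(rep = seq_len(config$reps), genotype = gs,
                        condition = cs, experiment = es,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_plants <- nrow(design)
  gi <- match(design$genotype, gs)
  ci <- match(design$condition, cs)
  ei <- match(design$experiment, es)
  plant_id <- sprintf("g%s_%s_e%s_r%d", design$genotype, design$condition,
                      design$experiment, design$rep)

  # organ dry weights (mg), log-normal
  dw <- matrix(NA_real_, n_plants, 3, dimnames = list(NULL, ORGANS))
  for (o in 1:3) {
    mu <- log(config$dw_base_mg[o] * config$dw_condition_mult[cbind(ci, o)]) +
      dw_g[cbind(gi, o)] + dw_gc[cbind(gi, ci, o)] + dw_ge[cbind(gi, ei, o)] +
      dw_ce[cbind(ci, ei, o)] + dw_gce[cbind(gi, ci, ei, o)]
    dw[, o] <- exp(mu + stats::rnorm(n_plants, sd = sdw$residual))
  }

  # seed composition: position along the cell line, then orthogonal offset
  n_line <- config$seed_n_genotype[design$genotype] +
    config$seed_n_condition_shift[design$condition] +
    n_e[ei] + n_gc[cbind(gi, ci)] + n_ge[cbind(gi, ei)] + n_ce[cbind(ci, ei)] +
    n_gce[cbind(gi, ci, ei)] +
    stats::rnorm(n_plants, sd = sn$residual)
  d_true <- config$dsc_offsets[design$genotype] +
    d_gc[cbind(gi, ci)] + d_ge[cbind(gi, ei)] +
    stats::rnorm(n_plants, sd = sd_d$residual)
  line_idx <- match(paste(design$experiment, design$condition),
                    paste(lines$experiment, lines$condition))
  b <- lines$slope[line_idx]; a <- lines$intercept[line_idx]
  s <- sqrt(1 + b^2)
  seed_n <- n_line - d_true * b / s
  seed_c <- (a + b * n_line) + d_true / s

  # N allocation fractions -> organ N%; log-normal perturbation keeps the
  # near-zero heat-condition shares positive and proportionate
  frac_n <- config$alloc_n_target[ci, , drop = FALSE] *
    exp(matrix(stats::rnorm(n_plants * 3, sd = config$alloc_n_noise_sd * ns),
               n_plants, 3))
  frac_n <- frac_n / rowSums(frac_n)
  qty_n_seeds <- dw[, "seeds"] * seed_n / 100
  qty_n_total <- qty_n_seeds / frac_n[, 3]
  n_pct <- cbind(rosette = frac_n[, 1] * qty_n_total / dw[, "rosette"] * 100,
                 stem = frac_n[, 2] * qty_n_total / dw[, "stem"] * 100,
                 seeds = seed_n)

  # 15N label: dose split by remobilization fractions, atom% back-computed
  frac_15 <- config$alloc_15n_target[ci, , drop = FALSE] *
    exp(matrix(stats::rnorm(n_plants * 3, sd = config$alloc_15n_noise_sd * ns),
               n_plants, 3))
  frac_15 <- frac_15 / rowSums(frac_15)
  qty_n <- dw * n_pct / 100
  e_pct <- config$label_dose_mg * frac_15 / qty_n * 100
  a15 <- e_pct + config$a15_control_pct

  other_c <- matrix(config$other_c_pct +
                      stats::rnorm(n_plants * 2, sd = config$other_c_sd * ns),
                    n_plants, 2)
  c_pct <- cbind(rosette = other_c[, 1], stem = other_c[, 2], seeds = seed_c)

  records <- do.call(rbind, lapply(1:3, function(o) {
    data.frame(plant_id = plant_id, genotype = design$genotype,
               condition = design$condition, experiment = design$experiment,
               organ = ORGANS[o], dw_mg = dw[, o], n_pct = n_pct[, o],
               c_pct = c_pct[, o], a15_pct = a15[, o], row.names = NULL)
  }))
  records <- records[order(records$plant_id, match(records$organ, ORGANS)), ]
  rownames(records) <- NULL

  truth_plants <- data.frame(
    plant_id = plant_id, genotype = design$genotype,
    condition = design$condition, experiment = design$experiment,
    frac_n_rosette = frac_n[, 1], frac_n_stem = frac_n[, 2],
    frac_n_seeds = frac_n[, 3],
    frac_15n_rosette = frac_15[, 1], frac_15n_stem = frac_15[, 2],
    frac_15n_seeds = frac_15[, 3],
    seed_n_line = n_line, dsc_true = d_true,
    line_slope = b, line_intercept = a, row.names = NULL)

  list(dataset = nue_dataset(records,
                             a15_control_pct = config$a15_control_pct),
       truth = list(plants = truth_plants, lines = lines, config = config))
}

#' Simulate a single trait from the balanced random-effects model
#'
#' Draws y = mu + g + c + e + gc + ge + ce + gce + eps with every layer an
#' independent normal of the requested variance — the exact model the
#' method-of-moments equations in [anova_components()] assume, so component
#' recovery can be tested against known truth.
#'
#' @param components named variances: `sigma2_gen`, `sigma2_gxc`,
#'   `sigma2_gxe`, `sigma2_cxe`, `sigma2_gxcxe`, `sigma2_err`.
#' @param n_gen,n_cond,n_exp,reps design sizes (defaults 8 x 6 x 4 x 4).
#' @param cond_sd,exp_sd SDs of the condition and experiment main effects
#'   (free in the decomposition; default 0).
#' @param mean grand mean.
#' @param seed optional RNG seed.
#' @return data.frame: `genotype`, `condition`, `experiment`, `y`.
#' @export
simulate_trait_table <- function(components, n_gen = 8, n_cond = 6,
                                 n_exp = 4, reps = 4, cond_sd = 0,
                                 exp_sd = 0, mean = 0, seed = NULL) {
  need <- c("sigma2_gen", "sigma2_gxc", "sigma2_gxe", "sigma2_cxe",
            "sigma2_gxcxe", "sigma2_err")
  stopifnot(all(need %in% names(components)))
  if (!is.null(seed)) set.seed(seed)
  sd_of <- function(nm) sqrt(components[[nm]])
  g <- .draw(sd_of("sigma2_gen"), n_gen)
  cc <- .draw(cond_sd, n_cond)
  e <- .draw(exp_sd, n_exp)
  gc_ <- .draw(sd_of("sigma2_gxc"), c(n_gen, n_cond))
  ge <- .draw(sd_of("sigma2_gxe"), c(n_gen, n_exp))
  ce <- .draw(sd_of("sigma2_cxe"), c(n_cond, n_exp))
  gce <- .draw(sd_of("sigma2_gxcxe"), c(n_gen, n_cond, n_exp))
  design <- expand.grid(rep = seq_len(reps), genotype = seq_len(n_gen),
                        condition = seq_len(n_cond), experiment = seq_len(n_exp),
                        KEEP.OUT.ATTRS = FALSE)
  y <- mean + g[design$genotype] + cc[design$condition] + e[design$experiment] +
    gc_[cbind(design$genotype, design$condition)] +
    ge[cbind(design$genotype, design$experiment)] +
    ce[cbind(design$condition, design$experiment)] +
    gce[cbind(design$genotype, design$condition, design$experiment)] +
    stats::rnorm(nrow(design), sd = sd_of("sigma2_err"))
  data.frame(genotype = paste0("g", design$genotype),
             condition = paste0("c", design$condition),
             experiment = as.character(design$experiment), y = y)
}

#' Small deterministic hand-checkable fixture
#'
#' 2 genotypes x 2 conditions (control, heat) x 1 experiment x 2 replicate
#' plants, with round numbers chosen so every index can be verified by hand
#' (e.g. plant `g63_control_1_r1` has organ N pools of exactly 1, 5 and 4 mg,
#' so N allocations are 0.1/0.5/0.4). One heat plant is fully sterile (seed
#' DW 0) to exercise the degenerate guard. No RNG is involved.
#'
#' @return a [nue_dataset()].
#' @export
fixture_small <- function() {
  row <- function(id, g, cond, organ, dw, n, c, a15) {
    data.frame(plant_id = id, genotype = g, condition = cond,
               experiment = "1", organ = organ, dw_mg = dw, n_pct = n,
               c_pct = c, a15_pct = a15)
  }
  rec <- rbind(
    # clean control plant: QtyN = (1, 5, 4) mg, Qty15N fracs = (0.1, 0.4, 0.5)
    row("g63_control_1_r1", "63", "control", "rosette", 200, 0.5, 40, 0.4660),
    row("g63_control_1_r1", "63", "control", "stem", 1000, 0.5, 42, 0.4460),
    row("g63_control_1_r1", "63", "control", "seeds", 800, 0.5, 56, 0.4910),
    row("g63_control_1_r2", "63", "control", "rosette", 230, 2.5, 40, 0.4700),
    row("g63_control_1_r2", "63", "control", "stem", 1600, 2.8, 42, 0.4500),
    row("g63_control_1_r2", "63", "control", "seeds", 840, 4.0, 55.1, 0.4900),
    row("g401_control_1_r1", "401", "control", "rosette", 250, 2.4, 40, 0.4650),
    row("g401_control_1_r1", "401", "control", "stem", 1500, 2.9, 42, 0.4450),
    row("g401_control_1_r1", "401", "control", "seeds", 900, 4.3, 53.1, 0.4880),
    row("g401_control_1_r2", "401", "control", "rosette", 220, 2.6, 40, 0.4680),
    row("g401_control_1_r2", "401", "control", "stem", 1450, 2.7, 42, 0.4470),
    row("g401_control_1_r2", "401", "control", "seeds", 870, 4.5, 52.3, 0.4890),
    row("g63_heat_1_r1", "63", "heat", "rosette", 170, 0.8, 40, 0.9000),
    row("g63_heat_1_r1", "63", "heat", "stem", 900, 2.6, 42, 0.5500),
    row("g63_heat_1_r1", "63", "heat", "seeds", 20, 4.9, 51.5, 0.4200),
    row("g63_heat_1_r2", "63", "heat", "rosette", 185, 0.7, 40, 0.8800),
    row("g63_heat_1_r2", "63", "heat", "stem", 950, 2.5, 42, 0.5400),
    row("g63_heat_1_r2", "63", "heat", "seeds", 22, 4.8, 52.0, 0.4100),
    row("g401_heat_1_r1", "401", "heat", "rosette", 200, 0.8, 40, 0.8500),
    row("g401_heat_1_r1", "401", "heat", "stem", 1100, 2.4, 42, 0.5300),
    row("g401_heat_1_r1", "401", "heat", "seeds", 18, 5.0, 50.2, 0.4000),
    # fully sterile heat plant: no seed material at all
    row("g401_heat_1_r2", "401", "heat", "rosette", 190, 0.9, 40, 0.8700),
    row("g401_heat_1_r2", "401", "heat", "stem", 1050, 2.5, 42, 0.5350),
    row("g401_heat_1_r2", "401", "heat", "seeds", 0, 0, 0, NA))
  nue_dataset(rec)
}
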