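# Synthetic arrayed rescue screen -------------------------------------------
#
# Generative model: each library plate carries one pooled-guide well per gene
# plus scattered control wells, and is stamped into replicate assay plates.
# Per library well, cell number N is log-normal around a plate mean (plate
# effect), Firefly is gain * N with multiplicative measurement noise, baseline
# HiBiT follows a strictly increasing cubic in Firefly, and PROTAC treatment
# removes a fraction d of the HiBiT signal unless a rescue gene restores a
# fraction rho of the degraded span (treated = baseline * (1 - d + rho * d)).
# Infection failure is drawn per library-well position (the same viral
# aliquot is stamped into every replicate), which leaves Firefly at
# background level in all replicates of that well.

#' Configuration for the synthetic arrayed rescue screen
#'
#' Defaults emulate the screen design this package analyzes: a 943-gene
#' arrayed library with 3-4 pooled guides per gene in one well each,
#' triplicate 384-well assay plates, a strong global PROTAC degradation
#' factor (90 percent of reporter signal removed), log-normal cell-number
#' variation coupled into both reporters, per-plate gain effects, and a
#' gene-correlated infection-failure rate sized so that roughly one gene in
#' eight fails the Firefly QC gate.
#'
#' @param n_genes Number of library genes (one pooled well per gene per
#'   replicate).
#' @param guides_per_gene Integer range (length-2) of pooled guides per gene.
#' @param n_replicate_plates Number of replicate assay plates stamped from
#'   each library plate.
#' @param hit_genes Named numeric vector mapping gene identifiers to rescue
#'   fractions rho in (0, 1]; rho = 1 is full rescue. `NULL` for a null
#'   screen.
#' @param degradation_factor Fraction d in \[0, 1) of HiBiT removed by the
#'   PROTAC in non-rescued wells.
#' @param cellnum_lognormal_sigma Log-normal sigma of per-well cell number.
#' @param plate_effect_sigma Log-normal sigma of the per-assay-plate mean
#'   cell number and gain.
#' @param firefly_gain Firefly RLU per cell before plate effects.
#' @param hibit_firefly_curve Length-4 numeric, cubic coefficients
#'   (intercept, linear, quadratic, cubic) mapping Firefly RLU to baseline
#'   HiBiT RLU; must be strictly increasing over the simulated Firefly range.
#' @param measurement_cv Multiplicative coefficient of variation applied
#'   independently to each luminescence readout.
#' @param infection_failure_rate Probability that a library-well position
#'   fails infection (applied to all replicates of that well).
#' @param rho_jitter_kappa Beta concentration of per-well rescue-fraction
#'   jitter around the gene's rho (models unequal guide potency in the
#'   pool); `Inf` disables jitter.
#' @param base_cells Nominal cells per well at assay time.
#' @param bg_firefly,bg_hibit Background RLU levels of media-only and
#'   uninfected (puromycin-killed) control wells.
#' @param controls_per_plate Named integer vector: number of `media_ctrl`,
#'   `uninfected_ctrl`, `plate_pos_ctrl` and `nontargeting_ctrl` wells
#'   scattered on each plate.
#' @param seed Integer seed; fans out to per-plate substreams.
#' @return A validated list of class `screen_sim_config`.
#' @examples
#' cfg <- screen_sim_config(n_genes = 40, seed = 1)
#' @export
screen_sim_config <- function(n_genes = 943,
                              guides_per_gene = c(3L, 4L),
                              n_replicate_plates = 3L,
                              hit_genes = NULL,
                              degradation_factor = 0.9,
                              cellnum_lognormal_sigma = 0.15,
                              plate_effect_sigma = 0.1,
                              firefly_gain = 40,
                              hibit_firefly_curve = c(200, 1.5, 2e-5, 4e-10),
                              measurement_cv = 0.05,
                              infection_failure_rate = 0.12,
                              rho_jitter_kappa = 40,
                              base_cells = 500,
                              bg_firefly = 1500,
                              bg_hibit = 60,
                              controls_per_plate = c(media_ctrl = 4L,
                                                     uninfected_ctrl = 4L,
                                                     plate_pos_ctrl = 4L,
                                                     nontargeting_ctrl = 4L),
                              seed = 1L) {
  stopifnot(n_genes >= 1, n_replicate_plates >= 1,
            length(guides_per_gene) == 2L,
            guides_per_gene[1] >= 1, guides_per_gene[2] >= guides_per_gene[1],
            degradation_factor >= 0, degradation_factor < 1,
            cellnum_lognormal_sigma >= 0, plate_effect_sigma >= 0,
            firefly_gain > 0, length(hibit_firefly_curve) == 4L,
            measurement_cv >= 0,
            infection_failure_rate >= 0, infection_failure_rate <= 1,
            rho_jitter_kappa > 0, base_cells > 0,
            bg_firefly > 0, bg_hibit >= 0,
            all(names(controls_per_plate) %in% WELL_CLASSES[-1]))
  if (!is.null(hit_genes)) {
    if (is.null(names(hit_genes)) || any(names(hit_genes) == "")) {
      stop("hit_genes must be a named numeric vector (gene -> rho)")
    }
    if (any(hit_genes <= 0 | hit_genes > 1)) {
      stop("rescue fractions rho must lie in (0, 1]")
    }
  }
  cfg <- list(n_genes = as.integer(n_genes),
              guides_per_gene = as.integer(guides_per_gene),
              n_replicate_plates = as.integer(n_replicate_plates),
              hit_genes = hit_genes,
              degradation_factor = degradation_factor,
              cellnum_lognormal_sigma = cellnum_lognormal_sigma,
              plate_effect_sigma = plate_effect_sigma,
              firefly_gain = firefly_gain,
              hibit_firefly_curve = hibit_firefly_curve,
              measurement_cv = measurement_cv,
              infection_failure_rate = infection_failure_rate,
              rho_jitter_kappa = rho_jitter_kappa,
              base_cells = base_cells,
              bg_firefly = bg_firefly,
              bg_hibit = bg_hibit,
              controls_per_plate = controls_per_plate,
              seed = as.integer(seed))
  class(cfg) <- "screen_sim_config"
  validate_curve(cfg)
  cfg
}

# The cubic must be strictly increasing over the plausible Firefly range so
# the plate-polynomial normalization can remove all Firefly-coupled variation.
validate_curve <- function(cfg) {
  hi <- cfg$firefly_gain * cfg$base_cells *
    exp(3 * (cfg$cellnum_lognormal_sigma + cfg$plate_effect_sigma)) *
    (1 + 4 * cfg$measurement_cv)
  x <- seq(0, hi, length.out = 512L)
  b <- cfg$hibit_firefly_curve
  deriv <- b[2] + 2 * b[3] * x + 3 * b[4] * x^2
  if (any(deriv <= 0)) {
    stop("hibit_firefly_curve must be strictly increasing over the ",
         "simulated Firefly range [0, ", round(hi), "]")
  }
  invisible(cfg)
}

eval_cubic <- function(coef, x) {
  coef[1] + coef[2] * x + coef[3] * x^2 + coef[4] * x^3
}

# Derived integer substream seed, kept below 2^31.
substream_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 1021 * k) %% 2147483563 + 1
}

#' Build the arrayed library annotation of a simulated screen
#'
#' Deterministically assigns each gene a pool of guides (count drawn
#' uniformly from `guides_per_gene`) and a (library plate, well) position.
#'
#' @param config A [screen_sim_config()].
#' @return A list with `library` (a `screen_library`) and `layout` (data
#'   frame of per-gene plate/well positions and control-well positions per
#'   plate).
#' @export
build_library <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  set.seed(substream_seed(config$seed, 0L))
  n_ctrl <- sum(config$controls_per_plate)
  wells_per_plate <- 384L - n_ctrl
  n_plates <- ceiling(config$n_genes / wells_per_plate)
  all_wells <- as.vector(outer(LETTERS[1:16], sprintf("%02d", 1:24), paste0))

  genes <- sprintf("G%04d", seq_len(config$n_genes))
  n_guides <- sample(seq(config$guides_per_gene[1], config$guides_per_gene[2]),
                     config$n_genes, replace = TRUE)
  guide_lists <- lapply(seq_along(genes), function(i) {
    sprintf("%s_sg%d", genes[i], seq_len(n_guides[i]))
  })
  names(guide_lists) <- genes

  layout <- vector("list", n_plates)
  gene_idx <- 0L
  for (p in seq_len(n_plates)) {
    plate_id <- sprintf("LP%d", p)
    # scattered control layout: positions drawn once per plate
    ctrl_pos <- sample(all_wells, n_ctrl)
    ctrl_class <- rep(names(config$controls_per_plate),
                      times = config$controls_per_plate)
    lib_pos <- setdiff(all_wells, ctrl_pos)
    n_here <- min(wells_per_plate, config$n_genes - gene_idx)
    lib_pos <- sort(lib_pos)[seq_len(n_here)]
    plate_genes <- genes[gene_idx + seq_len(n_here)]
    gene_idx <- gene_idx + n_here
    layout[[p]] <- rbind(
      data.frame(plate_id = plate_id, well_id = lib_pos,
                 gene_id = plate_genes, well_class = "library",
                 stringsAsFactors = FALSE),
      data.frame(plate_id = plate_id, well_id = ctrl_pos,
                 gene_id = "", well_class = ctrl_class,
                 stringsAsFactors = FALSE))
  }
  list(library = new_screen_library(guide_lists),
       layout = do.call(rbind, layout))
}

#' Simulate an arrayed CRISPR rescue screen with known ground truth
#'
#' Generates per-well HiBiT and Firefly readouts for every assay plate of the
#' configured screen, together with the ground truth needed for
#' parameter-recovery tests: each well's true treated/baseline signal ratio,
#' per-gene hit labels and rescue fractions, and per-well infection-failure
#' labels. Identical configurations (including seed) give identical output.
#'
#' @param config A [screen_sim_config()].
#' @return A list of class `screen_sim` with elements `wells` (plate-well
#'   data frame, one row per well of every assay plate), `library` (a
#'   `screen_library`), `truth_wells` (per-well ground truth) and
#'   `truth_genes` (per-gene ground truth).
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 30, seed = 7))
#' head(sim$wells)
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  if (!is.null(config$hit_genes)) {
    genes_all <- sprintf("G%04d", seq_len(config$n_genes))
    unknown <- setdiff(names(config$hit_genes), genes_all)
    if (length(unknown) > 0L) {
      stop("hit gene(s) not in library: ", paste(unknown, collapse = ", "))
    }
  }
  lib <- build_library(config)
  layout <- lib$layout
  d <- config$degradation_factor

  rho_gene <- setNames(rep(NA_real_, config$n_genes),
                       sprintf("G%04d", seq_len(config$n_genes)))
  if (!is.null(config$hit_genes)) rho_gene[names(config$hit_genes)] <- config$hit_genes

  # infection failure per library-well position, shared across replicates
  set.seed(substream_seed(config$seed, 1L))
  is_lib_pos <- layout$well_class == "library"
  fail_pos <- rep(FALSE, nrow(layout))
  fail_pos[is_lib_pos] <-
    stats::runif(sum(is_lib_pos)) < config$infection_failure_rate

  plates <- unique(layout$plate_id)
  out <- vector("list", length(plates) * config$n_replicate_plates)
  k <- 0L
  for (p in seq_along(plates)) {
    pl <- layout[layout$plate_id == plates[p], , drop = FALSE]
    pl_fail <- fail_pos[layout$plate_id == plates[p]]
    for (r in seq_len(config$n_replicate_plates)) {
      k <- k + 1L
      set.seed(substream_seed(config$seed, 100L * p + r))
      n <- nrow(pl)
      plate_mult <- exp(stats::rnorm(1, 0, config$plate_effect_sigma))
      gain <- config$firefly_gain * exp(stats::rnorm(1, 0, config$plate_effect_sigma))
      cells <- config$base_cells * plate_mult *
        exp(stats::rnorm(n, 0, config$cellnum_lognormal_sigma))
      eps_f <- stats::rnorm(n, 0, config$measurement_cv)
      eps_h <- stats::rnorm(n, 0, config$measurement_cv)
      bg_mult_f <- 1 + stats::rnorm(n, 0, config$measurement_cv)
      u_fail <- stats::runif(n, 0.5, 1.1)

      is_lib <- pl$well_class == "library"
      is_bg <- pl$well_class %in% c("media_ctrl", "uninfected_ctrl")
      is_pos <- pl$well_class == "plate_pos_ctrl"
      is_nt <- pl$well_class == "nontargeting_ctrl"

      firefly <- numeric(n)
      hibit <- numeric(n)
      true_rel <- rep(NA_real_, n)

      # cell-bearing wells: library + functional controls
      alive <- (is_lib & !pl_fail) | is_pos | is_nt
      firefly[alive] <- gain * cells[alive] * (1 + eps_f[alive])
      baseline <- eval_cubic(config$hibit_firefly_curve, firefly[alive])

      rho_well <- rep(0, n)
      rho_well[is_pos] <- 1  # per-plate positive-control guides: full rescue
      gi <- match(pl$gene_id, names(rho_gene))
      hit_here <- is_lib & !is.na(gi) & !is.na(rho_gene[gi])
      if (any(hit_here)) {
        rho0 <- rho_gene[gi[hit_here]]
        if (is.finite(config$rho_jitter_kappa)) {
          kp <- config$rho_jitter_kappa
          a <- rho0 * kp
          b <- (1 - rho0) * kp
          # Beta(a, 0) is degenerate at 1 (full rescue stays full)
          jit <- ifelse(b <= 0, 1, stats::rbeta(sum(hit_here), a, pmax(b, 1e-12)))
          rho_well[hit_here] <- jit
        } else {
          rho_well[hit_here] <- rho0
        }
      }
      rel <- 1 - d + rho_well * d
      hibit[alive] <- baseline * rel[alive] * (1 + eps_h[alive])
      true_rel[alive] <- rel[alive]

      # media / uninfected controls and failed infections: background signal
      dead <- is_bg | (is_lib & pl_fail)
      firefly[dead & is_bg] <- config$bg_firefly * bg_mult_f[dead & is_bg]
      failed <- is_lib & pl_fail
      firefly[failed] <- config$bg_firefly * u_fail[failed]
      hibit[dead] <- config$bg_hibit * (1 + eps_h[dead])
      true_rel[failed] <- NA_real_

      guide_pool <- ifelse(pl$gene_id == "", "",
                           vapply(pl$gene_id, function(g) {
                             if (g == "") "" else
                               paste(lib$library$genes[[g]], collapse = ";")
                           }, character(1)))

      out[[k]] <- data.frame(
        plate_id = pl$plate_id,
        replicate_id = sprintf("R%d", r),
        well_id = pl$well_id,
        gene_id = pl$gene_id,
        guide_ids = guide_pool,
        well_class = pl$well_class,
        hibit_rlu = pmax(hibit, 0),
        firefly_rlu = pmax(firefly, 0),
        true_rel_change = true_rel,
        infection_fail = is_lib & pl_fail,
        stringsAsFactors = FALSE)
    }
  }
  all <- do.call(rbind, out)
  rownames(all) <- NULL
  wells <- all[PLATE_WELL_COLUMNS]
  truth_wells <- all[c("plate_id", "replicate_id", "well_id", "gene_id",
                       "true_rel_change", "infection_fail")]
  truth_genes <- data.frame(
    gene_id = names(rho_gene),
    is_hit = !is.na(rho_gene),
    rho = unname(rho_gene),
    infection_fail = names(rho_gene) %in%
      layout$gene_id[is_lib_pos][fail_pos[is_lib_pos]],
    stringsAsFactors = FALSE)
  structure(list(wells = wells,
                 library = lib$library,
                 truth_wells = truth_wells,
                 truth_genes = truth_genes,
                 config = config),
            class = "screen_sim")
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("screen_sim:", x$config$n_genes, "genes,",
      length(unique(paste(x$wells$plate_id, x$wells$replicate_id))),
      "assay plates,", nrow(x$wells), "wells;",
      sum(x$truth_genes$is_hit), "planted hit(s)\n")
  invisible(x)
}

# Dose-response and binding simulators ---------------------------------------

four_pl <- function(x, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (x / ec50)^hill)
}

#' Simulate a four-parameter logistic dose-response table
#'
#' Responses are `4PL(dose) * (1 + Normal(0, cv))`, with the convention that
#' `top` is the response as dose approaches zero when `hill > 0`.
#'
#' @param bottom,top Lower and upper plateaus.
#' @param ec50 Midpoint concentration (same units as `doses`).
#' @param hill Hill slope; must be non-zero.
#' @param doses Positive, strictly increasing dose vector.
#' @param cv Multiplicative noise coefficient of variation.
#' @param n_rep Technical replicates per dose.
#' @param seed Integer seed (required when `cv > 0`).
#' @return Data frame with columns `dose`, `response`, `replicate`.
#' @export
simulate_dose_response <- function(bottom, top, ec50, hill, doses,
                                   cv = 0, n_rep = 1L, seed = NULL) {
  if (hill == 0) stop("hill must be non-zero (degenerate curve)")
  stopifnot(ec50 > 0, all(doses > 0), !is.unsorted(doses, strictly = TRUE),
            cv >= 0, n_rep >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  dose <- rep(doses, times = n_rep)
  replicate <- rep(seq_len(n_rep), each = length(doses))
  mu <- four_pl(dose, bottom, top, ec50, hill)
  eps <- if (cv > 0) stats::rnorm(length(dose), 0, cv) else 0
  data.frame(dose = dose, response = mu * (1 + eps), replicate = replicate)
}

#' Simulate ratiometric flow-cytometry degradation data
#'
#' Emulates a dual-fluorescence degradation sensor read by flow cytometry:
#' the background-subtracted GFP/mCherry ratio follows a descending
#' four-parameter logistic with midpoint `dc50` (maximal fractional
#' degradation `dmax`), and the viable-gate fraction follows a descending
#' logistic with midpoint `gi50`.
#'
#' @param dc50 Degradation midpoint concentration.
#' @param gi50 Viability midpoint concentration; must be positive.
#' @param hills Length-2 Hill slopes (degradation, viability).
#' @param doses Positive, strictly increasing dose vector.
#' @param bg_gfp,bg_mch Background fluorescence of the parental line.
#' @param cv Multiplicative noise coefficient of variation.
#' @param seed Integer seed.
#' @param dmax Maximal fractional degradation in (0, 1].
#' @param dmso_ratio Background-subtracted GFP/mCherry ratio of untreated
#'   cells.
#' @param mch_level Median mCherry signal above background.
#' @param viable_top,viable_bottom Plateaus of the viable-gate fraction.
#' @return Data frame with columns `dose`, `median_gfp`, `median_mch`,
#'   `viable_fraction`.
#' @export
simulate_flow_ratiometric <- function(dc50, gi50, hills = c(1, 2), doses,
                                      bg_gfp = 100, bg_mch = 120,
                                      cv = 0, seed = NULL,
                                      dmax = 1, dmso_ratio = 2,
                                      mch_level = 5000,
                                      viable_top = 1, viable_bottom = 0.02) {
  if (gi50 <= 0) stop("gi50 must be positive")
  stopifnot(dc50 > 0, length(hills) == 2L, all(hills != 0),
            all(doses > 0), !is.unsorted(doses, strictly = TRUE),
            bg_gfp >= 0, bg_mch >= 0, cv >= 0,
            dmax > 0, dmax <= 1, dmso_ratio > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(doses)
  ratio <- dmso_ratio * four_pl(doses, 1 - dmax, 1, dc50, hills[1])
  viable <- four_pl(doses, viable_bottom, viable_top, gi50, hills[2])
  noise <- function() if (cv > 0) 1 + stats::rnorm(n, 0, cv) else 1
  mch <- (bg_mch + mch_level) * noise()
  gfp <- (bg_gfp + ratio * mch_level) * noise()
  data.frame(dose = doses,
             median_gfp = gfp,
             median_mch = mch,
             viable_fraction = pmin(pmax(viable * noise(), 0), 1))
}

#' Simulate a hook-effect (bell-shaped) ternary-complex isotherm
#'
#' Steady-state ternary complex response as the product of an ascending and a
#' descending hyperbola:
#' `R(c) = rmax * c / (kd1 + c) * kd2 / (kd2 + c) * (1 + Normal(0, cv))`.
#' The noise-free curve peaks at `sqrt(kd1 * kd2)` and falls back to zero at
#' saturating ligand (hook effect).
#'
#' @param kd1,kd2 Apparent dissociation constants of the ascending and
#'   descending transitions; positive.
#' @param rmax Response amplitude; positive.
#' @param concentrations Positive analyte concentrations.
#' @param cv Multiplicative noise coefficient of variation.
#' @param seed Integer seed.
#' @return Data frame with columns `conc`, `response`.
#' @export
simulate_ternary_isotherm <- function(kd1, kd2, rmax, concentrations,
                                      cv = 0, seed = NULL) {
  stopifnot(kd1 > 0, kd2 > 0, rmax > 0, all(concentrations > 0), cv >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  c_ <- concentrations
  mu <- rmax * c_ / (kd1 + c_) * kd2 / (kd2 + c_)
  eps <- if (cv > 0) stats::rnorm(length(c_), 0, cv) else 0
  data.frame(conc = c_, response = mu * (1 + eps))
}
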