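#' Synthetic assay-data generators
#'
#' Every estimator in the package has a matching generator that reproduces
#' the statistical structure of the corresponding wet-lab assay:
#' exponential adsorption decay with a non-adsorbable residual, delayed
#' burst one-step growth curves on a 3-min grid, Poisson plating noise at
#' an auto-selected countable dilution, Poisson-distributed resistant
#' colonies, and OD600 trajectories of phage-challenged broth cultures.
#' All generators are pure functions of (parameters, seed).
#'
#' @name simulate
NULL

#' Infection parameters for the kinetics generators
#'
#' @param k Adsorption rate constant (ml/min), >= 0.
#' @param r Residual non-adsorbable phage fraction in [0, 1].
#' @param latent Latent period (min), >= 0.
#' @param rise Duration of the linear burst rise (min), > 0.
#' @param burst Burst size (phage per infected cell), >= 0.
#' @param B Host concentration (cfu/ml), > 0.
#' @param moi Multiplicity of infection; initial phage p0 = moi * B.
#' @return List of class \code{"infection_params"}.
#' @export
infection_params <- function(k, r = 0, latent = 25, rise = 15, burst = 100,
                             B = 1e8, moi = 0.001) {
  if (k < 0 || r < 0 || r > 1 || latent < 0 || rise <= 0 || burst < 0 ||
      B <= 0 || moi <= 0) {
    pc_stop("invalid infection parameters (non-negative, r <= 1, rise > 0, B > 0, moi > 0)")
  }
  structure(list(k = k, r = r, latent = latent, rise = rise, burst = burst,
                 B = B, moi = moi, p0 = moi * B),
            class = "infection_params")
}

#' Ground-truth parameter presets for the two characterized phages
#'
#' Presets matching the published characterization of the two Acinetobacter
#' baumannii phages: Acibel004 (k = 1.2e-9 ml/min, 85% maximal adsorption,
#' latent period 27 min, burst size 125) and Acibel007 (k = 1.7e-9 ml/min,
#' 95% maximal adsorption, latent period 21 min, burst size 145), both
#' assayed at MOI 0.001 on a 1e8 cfu/ml host culture.
#'
#' @return Named list of \code{\link{infection_params}}.
#' @export
phage_presets <- function() {
  list(
    acibel004 = infection_params(k = 1.2e-9, r = 0.15, latent = 27,
                                 rise = 15, burst = 125, B = 1e8, moi = 0.001),
    acibel007 = infection_params(k = 1.7e-9, r = 0.05, latent = 21,
                                 rise = 15, burst = 145, B = 1e8, moi = 0.001)
  )
}

# Poisson plating at an auto-selected tenfold dilution: the plated count is
# kept in the countable 30-300 range whenever the expected titer allows,
# mirroring standard plaque-assay practice. Returns noisy titers.
plate_titer <- function(expected) {
  vapply(expected, function(mu) {
    if (mu <= 0) return(0)
    d <- 10^max(0, ceiling(log10(mu / 300)))
    stats::rpois(1L, mu / d) * d
  }, numeric(1))
}

#' Simulate an adsorption assay
#'
#' Expected free-phage titer P(t) = p0 (r + (1 - r) exp(-k B t)), observed
#' through Poisson plating noise at an auto-selected countable dilution.
#'
#' @param params An \code{\link{infection_params}}.
#' @param times Sampling times in minutes (default: the classical
#'   3, 5, 8, 10, 15, 20 min grid).
#' @param seed RNG seed.
#' @param n_replicates Independent assay replicates (default 3, the
#'   standard triplicate design).
#' @param noise Set \code{FALSE} for the noise-free expectation (single
#'   replicate).
#' @return A \code{\link{titer_series}}.
#' @export
simulate_adsorption <- function(params, times = c(3, 5, 8, 10, 15, 20),
                                seed = 1L, n_replicates = 3, noise = TRUE) {
  stopifnot(inherits(params, "infection_params"))
  if (length(times) == 0L) pc_stop("`times` must be non-empty")
  expected <- params$p0 * (params$r + (1 - params$r) * exp(-params$k * params$B * times))
  if (!noise) return(titer_series(times, expected))
  with_seed(seed, {
    titer_series(rep(times, times = n_replicates),
                 unlist(lapply(seq_len(n_replicates), function(i) plate_titer(expected))),
                 replicate = rep(seq_len(n_replicates), each = length(times)))
  })
}

#' Simulate a one-step growth assay
#'
#' Free-phage titer: baseline (= total phage input, unadsorbed carryover
#' plus infective centers) until the latent period ends, then a linear rise
#' over \code{rise} minutes to baseline + burst x infected cells, then a
#' plateau. Infected cells are the phage adsorbed during the 8-min
#' adsorption step: p0 x (1 - r) (1 - exp(-k B t_ads)). Observed through
#' the same Poisson plating model as \code{\link{simulate_adsorption}}.
#'
#' @param params An \code{\link{infection_params}}.
#' @param times Sampling grid in minutes (default every 3 min to 90 min).
#' @param seed RNG seed.
#' @param adsorption_time Length of the adsorption step (min, default 8).
#' @param n_replicates Independent assay replicates (default 3, the
#'   standard triplicate design).
#' @param noise Set \code{FALSE} for the noise-free expectation (single
#'   replicate).
#' @return A \code{\link{titer_series}} with attributes
#'   \code{infected_cells} and \code{baseline} (generator truth, for
#'   recovery tests).
#' @export
simulate_onestep <- function(params, times = seq(0, 90, by = 3), seed = 1L,
                             adsorption_time = 8, n_replicates = 3,
                             noise = TRUE) {
  stopifnot(inherits(params, "infection_params"))
  if (params$latent + params$rise > max(times)) {
    pc_stop("latent + rise must fall within the sampling range")
  }
  adsorbed_frac <- (1 - params$r) * (1 - exp(-params$k * params$B * adsorption_time))
  infected <- params$p0 * adsorbed_frac
  baseline <- params$p0
  amp <- params$burst * infected
  expected <- vapply(times, function(t) {
    if (t < params$latent) {
      baseline
    } else if (t < params$latent + params$rise) {
      baseline + amp * (t - params$latent) / params$rise
    } else {
      baseline + amp
    }
  }, numeric(1))
  out <- if (!noise) {
    titer_series(times, expected)
  } else {
    with_seed(seed, {
      titer_series(rep(times, times = n_replicates),
                   unlist(lapply(seq_len(n_replicates), function(i) plate_titer(expected))),
                   replicate = rep(seq_len(n_replicates), each = length(times)))
    })
  }
  attr(out, "infected_cells") <- infected
  attr(out, "baseline") <- baseline
  out
}

#' Simulate a resistant-mutant plating assay
#'
#' Colonies per replicate are Poisson(f x cells_plated): selection is
#' applied at plating, so counts follow simple Poisson sampling (no
#' Luria-Delbruck jackpot structure).
#'
#' @param f True resistant-mutant frequency in [0, 1].
#' @param cells_plated Cells plated per replicate, > 0.
#' @param n_replicates Number of replicate platings (default 3).
#' @param seed RNG seed.
#' @return A \code{\link{resistance_plating}} data frame.
#' @export
simulate_resistance <- function(f, cells_plated, n_replicates = 3, seed = 1L) {
  if (f < 0 || f > 1) pc_stop("`f` must lie in [0, 1]")
  if (cells_plated <= 0) pc_stop("`cells_plated` must be > 0")
  colonies <- with_seed(seed, stats::rpois(n_replicates, f * cells_plated))
  resistance_plating(colonies, cells_plated)
}

#' Broth-culture parameters for the Appelmans simulator
#'
#' Phenomenological mass-action model of a phage-challenged broth culture:
#' logistic host growth, infection at rate adsorption_k x S x P with burst
#' release, and a resistant subpopulation (initial fraction
#' \code{resistant_frequency}) that grows uninfected. OD600 is
#' proportional to total cells.
#'
#' @param growth_rate Host growth rate (per hour).
#' @param carrying_capacity Carrying capacity (cells/ml).
#' @param adsorption_k Adsorption rate constant (ml/h).
#' @param burst Burst size.
#' @param resistant_frequency Initial resistant fraction in [0, 1].
#' @param od_per_cell OD600 per cell/ml.
#' @return List of class \code{"broth_params"}.
#' @export
broth_params <- function(growth_rate = 0.9, carrying_capacity = 1e9,
                         adsorption_k = 7.2e-8, burst = 100,
                         resistant_frequency = 1e-7, od_per_cell = 1.25e-9) {
  if (growth_rate <= 0 || carrying_capacity <= 0 || adsorption_k <= 0 ||
      burst <= 0 || od_per_cell <= 0) {
    pc_stop("broth parameters must be positive")
  }
  if (resistant_frequency < 0 || resistant_frequency > 1) {
    pc_stop("`resistant_frequency` must lie in [0, 1]")
  }
  structure(list(growth_rate = growth_rate,
                 carrying_capacity = carrying_capacity,
                 adsorption_k = adsorption_k, burst = burst,
                 resistant_frequency = resistant_frequency,
                 od_per_cell = od_per_cell),
            class = "broth_params")
}

# Mass-action broth dynamics for one tube. Cells are partitioned by their
# resistance genotype over the (up to two) phages; phage i kills every
# genotype sensitive to i. Resistance loci are independent, so the
# double-resistant founder population in a mixture tube is the product of
# the two (small) single frequencies.
broth_tube_od <- function(pa, pb, p0_a, p0_b, n0, hours, od_read = NULL) {
  use_a <- !is.null(pa) && p0_a > 0
  use_b <- !is.null(pb) && p0_b > 0
  ref <- if (!is.null(pa)) pa else pb
  fa <- if (!is.null(pa)) pa$resistant_frequency else 0
  fb <- if (!is.null(pb)) pb$resistant_frequency else 0
  mu <- ref$growth_rate; K <- ref$carrying_capacity
  ba <- if (!is.null(pa)) pa$burst else 0
  bb <- if (!is.null(pb)) pb$burst else 0
  ka <- if (!is.null(pa)) pa$adsorption_k else 0
  kb <- if (!is.null(pb)) pb$adsorption_k else 0

  # genotype SS, RS, SR, RR (resistance to phage a / phage b)
  y0 <- c(
    Sss = n0 * (1 - fa) * (1 - fb),
    Srs = n0 * fa * (1 - fb),
    Ssr = n0 * (1 - fa) * fb,
    Srr = n0 * fa * fb,
    Pa = p0_a,
    Pb = p0_b
  )
  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    N <- y["Sss"] + y["Srs"] + y["Ssr"] + y["Srr"]
    logistic <- mu * (1 - N / K)
    kill_a <- if (use_a) ka * y["Pa"] else 0
    kill_b <- if (use_b) kb * y["Pb"] else 0
    dSss <- y["Sss"] * (logistic - kill_a - kill_b)
    dSrs <- y["Srs"] * (logistic - kill_b)
    dSsr <- y["Ssr"] * (logistic - kill_a)
    dSrr <- y["Srr"] * logistic
    susceptible_a <- y["Sss"] + y["Ssr"]
    susceptible_b <- y["Sss"] + y["Srs"]
    dPa <- if (use_a) (ba - 1) * ka * susceptible_a * y["Pa"] else 0
    dPb <- if (use_b) (bb - 1) * kb * susceptible_b * y["Pb"] else 0
    list(c(dSss, dSrs, dSsr, dSrr, dPa, dPb))
  }
  sol <- deSolve::ode(y = y0, times = c(0, hours), func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-4)
  if (anyNA(sol)) {
    pc_stop(sprintf("broth integration failed (NaN) for n0=%g, Pa=%g, Pb=%g",
                    n0, p0_a, p0_b),
            class = "phagechar_numerical_error")
  }
  rows <- match(hours, sol[, "time"])
  cells <- rowSums(pmax(sol[rows, c("Sss", "Srs", "Ssr", "Srr"), drop = FALSE], 0))
  ref$od_per_cell * cells
}

#' Simulate an Appelmans serial-dilution broth assay
#'
#' Integrates the mass-action broth model for every tube of the plan under
#' four conditions (each phage alone, the equal-titer mixture, and an
#' uninfected control), reading OD600 at the requested times with seeded
#' Gaussian read noise (sd 0.01, clamped at 0).
#'
#' @param params_a,params_b \code{\link{broth_params}} for the two phages.
#' @param plan A \code{\link{dilution_plan}}; the mixture splits the stock
#'   titer equally between the two phages.
#' @param hours Readout times in hours (default \code{c(24, 48)}).
#' @param n_replicates Replicate tubes per condition/dilution (default 3).
#' @param seed RNG seed.
#' @param read_noise_sd SD of the Gaussian OD read noise (default 0.01).
#' @return An \code{\link{od_table}} covering conditions \code{phage_a},
#'   \code{phage_b}, \code{mixture} and \code{control}.
#' @export
simulate_appelmans <- function(params_a, params_b, plan, hours = c(24, 48),
                               n_replicates = 3, seed = 1L,
                               read_noise_sd = 0.01) {
  stopifnot(inherits(params_a, "broth_params"), inherits(params_b, "broth_params"),
            inherits(plan, "dilution_plan"))
  n0 <- plan$bacteria
  rows <- list()
  for (e in plan$dilution_exponents) {
    p_full <- plan$stock_titer * 10^e
    od_a <- broth_tube_od(params_a, NULL, p_full, 0, n0, hours)
    od_b <- broth_tube_od(NULL, params_b, 0, p_full, n0, hours)
    od_m <- broth_tube_od(params_a, params_b, p_full / 2, p_full / 2, n0, hours)
    for (h in seq_along(hours)) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = c("phage_a", "phage_b", "mixture"),
        dilution_exponent = e,
        time_h = hours[h],
        od_true = c(od_a[h], od_b[h], od_m[h])
      )
    }
  }
  od_c <- broth_tube_od(params_a, NULL, 0, 0, n0, hours)
  for (h in seq_along(hours)) {
    rows[[length(rows) + 1L]] <- data.frame(
      condition = "control", dilution_exponent = NA_integer_,
      time_h = hours[h], od_true = od_c[h]
    )
  }
  base <- do.call(rbind, rows)
  full <- base[rep(seq_len(nrow(base)), each = n_replicates), ]
  full$replicate <- rep(seq_len(n_replicates), times = nrow(base))
  full$od600 <- with_seed(seed, {
    pmax(full$od_true + stats::rnorm(nrow(full), 0, read_noise_sd), 0)
  })
  full$od_true <- NULL
  rownames(full) <- NULL
  od_table(full)
}

random_dna <- function(length, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), length, replace = TRUE, prob = probs), collapse = "")
}

#' Simulate genomes for fingerprinting tests
#'
#' Generates i.i.d.-base genomes at a target GC content, optionally
#' planting the GCGC restriction site at a fixed density (evenly spaced
#' with positional jitter), and optionally deriving clones by insertion or
#' deletion edits. Clone inserts are drawn from a G-free alphabet and
#' placed away from existing sites, so an insertion changes band lengths
#' without creating or destroying sites.
#'
#' @param n Number of independent genomes.
#' @param length Genome length (bp).
#' @param gc Target GC fraction in (0, 1).
#' @param site_density Planted GCGC sites per bp (e.g. 1e-3), or NULL for
#'   none.
#' @param clone_edits Optional list of edit lists, one per clone to derive
#'   from the FIRST genome; each edit is
#'   \code{list(type = "insert"|"delete", length = <bp>)}.
#' @param seed RNG seed.
#' @return Named list of \code{\link{genome_record}}s (\code{g1..gn},
#'   then \code{g1_cloneK} for any clones).
#' @export
simulate_genomes <- function(n, length, gc = 0.5, site_density = NULL,
                             clone_edits = NULL, seed = 1L) {
  if (gc <= 0 || gc >= 1) pc_stop("`gc` must lie in (0, 1)")
  if (length <= 0) pc_stop("`length` must be > 0")
  with_seed(seed, {
    genomes <- list()
    for (i in seq_len(n)) {
      s <- random_dna(length, gc)
      if (!is.null(site_density)) {
        n_sites <- max(1L, floor(length * site_density))
        spacing <- length / (n_sites + 1)
        pos <- round(spacing * seq_len(n_sites) +
                       stats::runif(n_sites, -spacing / 3, spacing / 3))
        pos <- pmin(pmax(pos, 1), length - 3L)
        for (p in pos) substr(s, p, p + 3L) <- "GCGC"
      }
      genomes[[paste0("g", i)]] <- genome_record(paste0("g", i), s)
    }
    if (!is.null(clone_edits)) {
      base_seq <- genomes[["g1"]]$sequence
      site_pos <- gregexpr("GCGC", base_seq, fixed = TRUE)[[1]]
      for (kk in seq_along(clone_edits)) {
        edit <- clone_edits[[kk]]
        s <- base_seq
        L <- nchar(s)
        # candidate positions clear of any site by one motif length
        repeat {
          at <- sample.int(L - 1L, 1L)
          if (all(site_pos < 0) || all(abs(at - site_pos) > 8L)) break
        }
        if (edit$type == "insert") {
          ins <- paste(sample(c("A", "C", "T"), edit$length, replace = TRUE),
                       collapse = "")
          s <- paste0(substr(s, 1, at), ins, substr(s, at + 1L, L))
        } else if (edit$type == "delete") {
          stop_at <- min(at + edit$length - 1L, L - 1L)
          s <- paste0(substr(s, 1, at - 1L), substr(s, stop_at + 1L, L))
        } else {
          pc_stop("edit type must be 'insert' or 'delete'")
        }
        id <- paste0("g1_clone", kk)
        genomes[[id]] <- genome_record(id, s)
      }
    }
    genomes
  })
}
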