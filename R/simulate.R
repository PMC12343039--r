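## Ledger generator. Emulates the statistical structure the accounting
## assumes: a regional ambient particle pool, size-selective capture onto
## loricae (particles of roughly 20-30% of the lorica oral diameter are
## preferred), and a shift to ubiquitous diatom fragments when coccoliths are
## scarce. Capture is a multiplicative up-weighting inside the selectivity
## window, not a hard filter: real loricae carry small and large liths
## simultaneously.

## evaluate an expression with a private, restored RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Regional ambient particle assemblage
#'
#' Built-in ambient pools encode the qualitative regional patterns the
#' accounting was developed against: a temperate (North Atlantic-like) pool
#' ranked Emiliania > Calcidiscus > Gephyrocapsa > Syracosphaera >
#' Coccolithus with small whole diatom cells; a polar pool dominated by
#' Emiliania (Calcidiscus well under 20%, Coccolithus rare) with abundant
#' diatom fragments; and a tropical pool of small light liths
#' (Florisphaera, Gladiolithus, Umbilicosphaera, Syracosphaera) plus
#' Rhabdosphaera. Relative abundances are normalised to sum to 1.
#'
#' @param region one of `"temperate"`, `"polar"`, `"tropical"`, or a
#'   data.frame with columns `taxon`, `particle_kind`, `abundance` (and
#'   optionally `size_um`) for a custom pool.
#' @param coccolith_availability scalar in `[0, 1]`: ambient coccolith supply;
#'   below the capture model's scarcity threshold the coccolith pool is
#'   scaled by this factor and diatom particles take over (see
#'   [capture_model()]).
#' @param reference a [ballast_reference()] supplying characteristic particle
#'   sizes where the pool does not state them.
#' @return An object of class `ambient_assemblage`: list with `pool`
#'   (data.frame: taxon, particle_kind, abundance, size_um), `region`,
#'   `coccolith_availability`.
#' @export
ambient_assemblage <- function(region = c("temperate", "polar", "tropical"),
                               coccolith_availability = 1,
                               reference = ballast_reference()) {
  stopifnot(coccolith_availability >= 0, coccolith_availability <= 1)
  if (is.data.frame(region)) {
    pool <- region
    region_name <- attr(region, "region") %||% "custom"
  } else {
    region_name <- match.arg(region)
    pool <- switch(region_name,
      temperate = data.frame(
        taxon = c("Emiliania", "Calcidiscus", "Gephyrocapsa", "Syracosphaera",
                  "Coccolithus", "Fragilariopsis pseudonana"),
        particle_kind = c(rep("coccolith", 5), "diatom_cell"),
        abundance = c(0.50, 0.18, 0.12, 0.08, 0.04, 0.08)),
      polar = data.frame(
        taxon = c("Emiliania", "Calcidiscus", "Coccolithus",
                  "Fragilariopsis", "Chaetoceros", "Pseudo-nitzschia",
                  "Thalassiothrix", "Coscinodiscus", "Eucampia"),
        particle_kind = c(rep("coccolith", 3), rep("diatom_fragment", 6)),
        abundance = c(0.60, 0.10, 0.01, 0.10, 0.06, 0.05, 0.04, 0.03, 0.01)),
      tropical = data.frame(
        taxon = c("Emiliania", "Umbilicosphaera", "Florisphaera",
                  "Gladiolithus", "Syracosphaera", "Rhabdosphaera",
                  "Calcidiscus"),
        particle_kind = rep("coccolith", 7),
        abundance = c(0.30, 0.18, 0.15, 0.12, 0.12, 0.08, 0.05)))
  }
  if (any(pool$abundance < 0)) abort("abundances must be non-negative")
  if (sum(pool$abundance) <= 0) abort("degenerate ambient: all-zero abundance")
  pool$abundance <- pool$abundance / sum(pool$abundance)
  if (is.null(pool$size_um)) pool$size_um <- NA_real_
  miss <- is.na(pool$size_um)
  pool$size_um[miss] <- mapply(
    particle_size_key, pool$taxon[miss],
    ifelse(pool$particle_kind[miss] == "coccolith", "coccolith", "diatom"),
    MoreArgs = list(reference = reference))
  if (any(is.na(pool$size_um) | pool$size_um <= 0))
    abort("every pool particle needs a positive characteristic size")
  structure(list(pool = pool, region = region_name,
                 coccolith_availability = coccolith_availability),
            class = "ambient_assemblage")
}

#' Size-selective capture model
#'
#' @param window selectivity window as a fraction of the lorica oral
#'   diameter; particles whose size falls inside `window * D` are up-weighted.
#'   Default `c(0.20, 0.30)`, the preferred prey-size band relative to lorica
#'   diameter.
#' @param strength selectivity strength `>= 0`: an in-window particle's
#'   capture weight is multiplied by `1 + strength`; 0 means non-selective
#'   capture, recovering ambient proportions exactly.
#' @param scarcity_threshold coccolith availability below which the coccolith
#'   pool is down-scaled by the availability and capture shifts to diatom
#'   particles (default 0.25).
#' @param particles_per_lorica mean of the per-lorica particle count
#'   distribution (default 100).
#' @param count_model `"poisson"` (default) or `"nbinom"` for overdispersed
#'   counts.
#' @param nb_size negative-binomial size (dispersion) parameter when
#'   `count_model = "nbinom"`.
#' @return a list of class `capture_model`.
#' @export
capture_model <- function(window = c(0.20, 0.30), strength = 1,
                          scarcity_threshold = 0.25,
                          particles_per_lorica = 100,
                          count_model = c("poisson", "nbinom"), nb_size = 5) {
  stopifnot(length(window) == 2L, window[1] < window[2],
            window[1] > 0, window[2] <= 1, strength >= 0,
            scarcity_threshold >= 0, scarcity_threshold <= 1,
            particles_per_lorica >= 0)
  structure(list(window = window, strength = strength,
                 scarcity_threshold = scarcity_threshold,
                 particles_per_lorica = particles_per_lorica,
                 count_model = match.arg(count_model), nb_size = nb_size),
            class = "capture_model")
}

## ambient pool after the coccolith-scarcity shift
shifted_pool <- function(ambient, model) {
  pool <- ambient$pool
  a <- ambient$coccolith_availability
  if (a < model$scarcity_threshold) {
    cocc <- pool$particle_kind == "coccolith"
    pool$abundance[cocc] <- pool$abundance[cocc] * a
    if (sum(pool$abundance) <= 0)
      abort("degenerate ambient: scarcity shift removed all particles")
    pool$abundance <- pool$abundance / sum(pool$abundance)
  }
  pool
}

#' Capture weights for one lorica
#'
#' Probability that the next captured particle is of each pool class:
#' ambient relative abundance times a selectivity factor `1 + strength` for
#' particles whose size falls within the selectivity window of the lorica
#' oral diameter, normalised to sum to 1. With `strength = 0` the weights
#' equal the ambient proportions exactly.
#'
#' @param sizes positive particle sizes (um).
#' @param abundances ambient relative abundances (same length).
#' @param oral_diameter lorica oral diameter (um).
#' @param model a [capture_model()].
#' @return numeric vector of normalised capture probabilities.
#' @export
#' @examples
#' capture_weights(c(9, 3.5), c(0.5, 0.5), 40, capture_model(strength = 1))
#' # 9 um is inside 20-30% of 40 um -> weights 2/3, 1/3
capture_weights <- function(sizes, abundances, oral_diameter, model) {
  stopifnot(length(sizes) == length(abundances), all(sizes > 0),
            all(abundances >= 0), oral_diameter > 0)
  if (sum(abundances) <= 0) abort("degenerate ambient: all-zero abundance")
  rel <- sizes / oral_diameter
  s <- 1 + model$strength * (rel >= model$window[1] & rel <= model$window[2])
  w <- abundances * s
  w / sum(w)
}

#' Simulation parameters
#'
#' @param n_loricae number of loricae to generate (>= 1).
#' @param seed integer seed; mandatory, the generator is fully reproducible.
#' @param tintinnid_taxon name placed in the lorica metadata.
#' @param oral_diameter_mean,oral_diameter_sd oral diameter distribution
#'   (um); draws are truncated below at 20% of the mean.
#' @param ambient an [ambient_assemblage()].
#' @param capture a [capture_model()].
#' @param locality metadata label.
#' @return a list of class `simulation_params`.
#' @export
simulation_params <- function(n_loricae, seed,
                              tintinnid_taxon = "Tintinnid sp.",
                              oral_diameter_mean = 20, oral_diameter_sd = 2,
                              ambient = ambient_assemblage("temperate"),
                              capture = capture_model(),
                              locality = "simulated") {
  stopifnot(n_loricae >= 1, is.numeric(seed), length(seed) == 1L,
            oral_diameter_mean > 0, oral_diameter_sd >= 0,
            inherits(ambient, "ambient_assemblage"),
            inherits(capture, "capture_model"))
  structure(list(n_loricae = as.integer(n_loricae), seed = as.integer(seed),
                 tintinnid_taxon = tintinnid_taxon,
                 oral_diameter_mean = oral_diameter_mean,
                 oral_diameter_sd = oral_diameter_sd,
                 ambient = ambient, capture = capture, locality = locality),
            class = "simulation_params")
}

#' Simulate a particle ledger
#'
#' For each lorica: draws an oral diameter, a particle count (Poisson or
#' negative binomial), and particle classes multinomially from
#' [capture_weights()] applied to the (scarcity-shifted) ambient pool.
#' Coccoliths are emitted as `count` observations, diatom particles as
#' `biovolume_um3` observations (count x reference biovolume). Identical
#' parameters and seed give identical ledgers.
#'
#' @param params a [simulation_params()].
#' @param reference a [ballast_reference()].
#' @return a validated [lorica_ledger()].
#' @export
#' @examples
#' led <- simulate_ledger(simulation_params(5, seed = 1))
#' led
simulate_ledger <- function(params, reference = ballast_reference()) {
  stopifnot(inherits(params, "simulation_params"))
  pool <- shifted_pool(params$ambient, params$capture)
  region <- if (params$ambient$region %in% REGION_CLASSES)
    params$ambient$region else "temperate"
  with_seed(params$seed, {
    n <- params$n_loricae
    D <- pmax(rnorm(n, params$oral_diameter_mean, params$oral_diameter_sd),
              0.2 * params$oral_diameter_mean)
    D <- round(D, 2)
    N <- switch(params$capture$count_model,
                poisson = rpois(n, params$capture$particles_per_lorica),
                nbinom = rnbinom(n, size = params$capture$nb_size,
                                 mu = params$capture$particles_per_lorica))
    obs <- NULL
    for (i in seq_len(n)) {
      id <- sprintf("SIM%04d", i)
      if (N[i] == 0) next
      w <- capture_weights(pool$size_um, pool$abundance, D[i], params$capture)
      counts <- as.integer(rmultinom(1, N[i], w))
      hit <- which(counts > 0)
      if (!length(hit)) next
      is_cocc <- pool$particle_kind[hit] == "coccolith"
      qty <- as.numeric(counts[hit])
      if (any(!is_cocc))
        qty[!is_cocc] <- qty[!is_cocc] * diatom_biovolume(
          pool$taxon[hit][!is_cocc], pool$particle_kind[hit][!is_cocc],
          reference)
      obs <- rbind(obs, data.frame(
        lorica_id = id,
        particle_taxon = pool$taxon[hit],
        particle_kind = pool$particle_kind[hit],
        quantity_type = ifelse(is_cocc, "count", "biovolume_um3"),
        quantity = qty))
    }
    loricae <- data.frame(
      lorica_id = sprintf("SIM%04d", seq_len(n)),
      tintinnid_taxon = params$tintinnid_taxon,
      locality = params$locality, region_class = region,
      oral_diameter_um = D, bowl_length_um = NA_real_,
      n_loricae = 1L, group_label = NA_character_,
      printed_total_pg = NA_real_)
    lorica_ledger(loricae, obs %||% data.frame(), reference = reference,
                  source = paste0("simulated(seed=", params$seed, ")"))
  })
}

#' Parameter-recovery experiment
#'
#' Simulates a ledger, runs the full ballast accounting on it, and compares
#' the estimated mean total (and CaCO3) ballast per lorica against the
#' generator's closed-form expectation
#' `E[B] = E[count] * sum_i p_i * m_i`, where `p` are the capture
#' probabilities (averaged over the oral-diameter distribution by quadrature)
#' and `m_i` the per-particle masses. Reports z-scores
#' `(estimate - expectation) / SE`.
#'
#' @param params a [simulation_params()] with `n_loricae >= 100`.
#' @param reference a [ballast_reference()].
#' @return An object of class `recovery_report`: data.frame with columns
#'   `quantity`, `expected`, `estimated`, `se`, `z`; the simulated fit is
#'   attached as attribute `fit`.
#' @export
recovery_experiment <- function(params, reference = ballast_reference()) {
  stopifnot(inherits(params, "simulation_params"))
  if (params$n_loricae < 100)
    abort("recovery_experiment needs n_loricae >= 100")
  pool <- shifted_pool(params$ambient, params$capture)
  ## expected capture probabilities, integrating over the D distribution
  Dgrid <- if (params$oral_diameter_sd > 0)
    pmax(stats::qnorm(stats::ppoints(201), params$oral_diameter_mean,
                      params$oral_diameter_sd),
         0.2 * params$oral_diameter_mean)
  else params$oral_diameter_mean
  W <- matrix(vapply(Dgrid, function(D)
    capture_weights(pool$size_um, pool$abundance, D, params$capture),
    numeric(nrow(pool))), nrow = nrow(pool))
  p <- rowMeans(W)
  is_cocc <- pool$particle_kind == "coccolith"
  m <- numeric(nrow(pool))
  if (any(is_cocc)) m[is_cocc] <- lith_mass(pool$taxon[is_cocc], reference)
  if (any(!is_cocc)) m[!is_cocc] <- fragment_silica_mass(
    diatom_biovolume(pool$taxon[!is_cocc], pool$particle_kind[!is_cocc],
                     reference),
    reference$constants)
  EN <- params$capture$particles_per_lorica
  expected_total <- EN * sum(p * m)
  expected_caco3 <- EN * sum(p[is_cocc] * m[is_cocc])

  fit <- ballast(simulate_ledger(params, reference), reference)
  e <- fit$estimates
  zrow <- function(quantity, expected, x) {
    est <- mean(x)
    se <- pop_sd(x) / sqrt(length(x))
    z <- if (se == 0) ifelse(est == expected, 0, Inf) else (est - expected) / se
    data.frame(quantity = quantity, expected = expected, estimated = est,
               se = se, z = z)
  }
  out <- rbind(zrow("total_pg", expected_total, e$total_pg),
               zrow("caco3_pg", expected_caco3, e$caco3_pg))
  structure(out, class = c("recovery_report", "data.frame"), fit = fit)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Generator-vs-pipeline recovery (n =",
      nrow(attr(x, "fit")$estimates), "loricae)\n")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}
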