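## Reference masses, biovolumes and conversion constants.
##
## The whole accounting rests on two conversions:
##   * coccolith CaCO3:  mass = lith count x per-lith mass (pg CaCO3)
##   * diatom silica:    mass = biovolume (um^3) x 0.0005 pmol Si um^-3 x 28 pg pmol^-1
## The per-lith masses and per-fragment biovolumes are literature values; they
## are packaged as defaults and fully overridable from a YAML/JSON config.

#' Built-in particle mass reference
#'
#' Returns the packaged reference of per-lith coccolith CaCO3 masses (pg),
#' diatom particle biovolumes (um^3), the biovolume-to-silica conversion
#' constants, and the default taxon aliases. All values are user-overridable:
#' edit the returned object or supply a config file via [read_reference()].
#'
#' Default per-lith masses (pg CaCO3): Emiliania 4, Gladiolithus 4,
#' Syracosphaera 10, Umbilicosphaera 16, Florisphaera 20, Rhabdosphaera 60,
#' Calcidiscus 124, Helicosphaera 140, Coccolithus 152. Default diatom-particle
#' biovolumes (um^3): Pseudo-nitzschia fragment 25, Chaetoceros setae 40,
#' Fragilariopsis fragment 63, Thalassiothrix fragment 100, Eucampia cribrum
#' 250, Coscinodiscus cribrum 375; whole cells of Fragilariopsis pseudonana
#' 100. Default aliases map taxa without a published per-lith mass onto a
#' morphologically analogous mass class (Gephyrocapsa and Alisphaera onto the
#' Emiliania class, Coronosphaera onto Syracosphaera). Umbellosphaera and
#' Calciosolenia deliberately carry no default mass: their contributions must
#' be entered as `mass_pg` observations.
#'
#' @return An object of class `ballast_reference`: a list with elements
#'   `coccoliths` (data.frame: taxon, lith_mass_pg, size_min_um, size_max_um,
#'   shape_class, source), `diatoms` (data.frame: taxon, particle_kind,
#'   biovolume_um3, size_um), `constants` (list: si_pmol_per_um3,
#'   si_pg_per_pmol, lorica_dry_weight_pg, lorica_dry_weight_sd_pg) and
#'   `aliases` (named character vector, alias -> reference taxon).
#' @seealso [lith_mass()], [fragment_silica_mass()], [read_reference()]
#' @export
#' @examples
#' ref <- ballast_reference()
#' ref$coccoliths[ref$coccoliths$taxon == "Calcidiscus", "lith_mass_pg"]  # 124
ballast_reference <- function() {
  path <- system.file("extdata", "reference.yaml", package = "loricaballast",
                      mustWork = TRUE)
  read_reference(path)
}

#' Read a particle mass reference from YAML or JSON
#'
#' @param path path to a config file; format is inferred from the extension
#'   (`.yaml`/`.yml` or `.json`). Top-level keys: `coccoliths`, `diatom_particles`,
#'   `constants`, `aliases`.
#' @return A `ballast_reference` object; see [ballast_reference()].
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) abort("reference config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  reference_from_config(cfg)
}

reference_from_config <- function(cfg) {
  cocc <- do.call(rbind, lapply(names(cfg$coccoliths), function(tx) {
    e <- cfg$coccoliths[[tx]]
    if (is.numeric(e) && length(e) == 1L) e <- list(lith_mass_pg = e)
    data.frame(taxon = tx,
               lith_mass_pg = as.numeric(e$lith_mass_pg),
               size_min_um = as.numeric(e$size_min_um %||% NA),
               size_max_um = as.numeric(e$size_max_um %||% NA),
               shape_class = as.character(e$shape_class %||% NA),
               source = as.character(e$source %||% NA))
  }))
  diat <- do.call(rbind, lapply(cfg$diatom_particles, function(e) {
    data.frame(taxon = as.character(e$taxon),
               particle_kind = as.character(e$particle_kind),
               biovolume_um3 = as.numeric(e$biovolume_um3),
               size_um = as.numeric(e$size_um %||% NA))
  }))
  const <- list(
    si_pmol_per_um3 = as.numeric(cfg$constants$si_pmol_per_um3 %||% 5e-4),
    si_pg_per_pmol = as.numeric(cfg$constants$si_pg_per_pmol %||% 28),
    lorica_dry_weight_pg = as.numeric(cfg$constants$lorica_dry_weight_pg %||% 40000),
    lorica_dry_weight_sd_pg = as.numeric(cfg$constants$lorica_dry_weight_sd_pg %||% 20000)
  )
  aliases <- unlist(cfg$aliases %||% list())
  ref <- structure(list(coccoliths = cocc, diatoms = diat,
                        constants = const, aliases = aliases),
                   class = "ballast_reference")
  validate_reference(ref)
  ref
}

validate_reference <- function(ref) {
  with(ref, {
    if (anyDuplicated(coccoliths$taxon))
      abort("duplicate coccolith taxon in reference")
    if (anyDuplicated(paste(diatoms$taxon, diatoms$particle_kind)))
      abort("duplicate (taxon, particle_kind) in diatom reference")
    if (any(coccoliths$lith_mass_pg <= 0))
      abort("lith masses must be strictly positive")
    if (any(diatoms$biovolume_um3 <= 0))
      abort("diatom biovolumes must be strictly positive")
    ok <- is.na(coccoliths$size_min_um) | is.na(coccoliths$size_max_um) |
      coccoliths$size_min_um <= coccoliths$size_max_um
    if (!all(ok)) abort("coccolith size range min > max")
    if (any(unlist(constants) <= 0)) abort("constants must be strictly positive")
    bad <- setdiff(unname(aliases), coccoliths$taxon)
    if (length(bad)) abort("alias target not in reference: ", paste(bad, collapse = ", "))
  })
  invisible(ref)
}

#' Write a particle mass reference to YAML or JSON
#'
#' Inverse of [read_reference()]; a written-then-reread reference reproduces
#' the original masses exactly.
#'
#' @param reference a `ballast_reference` object.
#' @param path output path; `.json` selects JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  stopifnot(inherits(reference, "ballast_reference"))
  cocc <- reference$coccoliths
  cfg <- list(
    coccoliths = setNames(lapply(seq_len(nrow(cocc)), function(i) {
      e <- as.list(cocc[i, c("lith_mass_pg", "size_min_um", "size_max_um",
                             "shape_class", "source")])
      e[!vapply(e, function(v) is.na(v), logical(1))]
    }), cocc$taxon),
    diatom_particles = lapply(seq_len(nrow(reference$diatoms)), function(i) {
      e <- as.list(reference$diatoms[i, ])
      e[!vapply(e, function(v) is.na(v), logical(1))]
    }),
    constants = reference$constants,
    aliases = as.list(reference$aliases)
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path, precision = 15L)
  }
  invisible(path)
}

## Resolve a (possibly aliased) coccolith taxon to its reference taxon, or NA.
resolve_coccolith <- function(taxon, reference) {
  out <- ifelse(taxon %in% reference$coccoliths$taxon, taxon,
                unname(reference$aliases[taxon]))
  as.character(out)
}

#' Per-lith CaCO3 mass of a coccolith taxon
#'
#' Looks up the per-lith mass (pg CaCO3), resolving aliases (e.g. Gephyrocapsa
#' resolves to the Emiliania mass class). Vectorised over `taxon`.
#'
#' @param taxon character vector of coccolith taxon names.
#' @param reference a `ballast_reference`; defaults to the packaged one.
#' @return numeric vector of per-lith masses in pg CaCO3.
#' @export
#' @examples
#' lith_mass(c("Emiliania", "Coccolithus"))   # 4 152
#' lith_mass("Gephyrocapsa")                  # 4 (alias)
lith_mass <- function(taxon, reference = ballast_reference()) {
  resolved <- resolve_coccolith(taxon, reference)
  if (anyNA(resolved)) {
    abort("no lith mass or alias for coccolith taxon ",
          paste(sq(unique(taxon[is.na(resolved)])), collapse = ", "))
  }
  m <- setNames(reference$coccoliths$lith_mass_pg, reference$coccoliths$taxon)
  unname(m[resolved])
}

## Biovolume (um^3) of one diatom particle of a given taxon and kind
## (kind uses the observation vocabulary: diatom_fragment / diatom_cell).
diatom_biovolume <- function(taxon, particle_kind, reference = ballast_reference()) {
  kind <- c(diatom_fragment = "fragment", diatom_cell = "whole_cell")[particle_kind]
  key <- paste(taxon, kind)
  tab <- setNames(reference$diatoms$biovolume_um3,
                  paste(reference$diatoms$taxon, reference$diatoms$particle_kind))
  out <- unname(tab[key])
  if (anyNA(out)) {
    abort("no reference biovolume for diatom particle ",
          paste(sq(unique(key[is.na(out)])), collapse = ", "))
  }
  out
}

#' Biogenic silica mass of a diatom particle from its biovolume
#'
#' Converts a biovolume (um^3) to biogenic silica (pg) as
#' `biovolume * si_pmol_per_um3 * si_pg_per_pmol`; with the default constants
#' (0.0005 pmol Si per um^3, 28 pg Si per pmol) this is 0.014 pg per um^3, so
#' a 100 um^3 particle carries 1.4 pg silica. Linear in the biovolume.
#'
#' @param biovolume numeric vector of biovolumes (um^3), all `>= 0`.
#' @param constants the `constants` element of a [ballast_reference()].
#' @return numeric vector of silica masses (pg).
#' @export
#' @examples
#' fragment_silica_mass(100)  # 1.4
#' fragment_silica_mass(375)  # 5.25
fragment_silica_mass <- function(biovolume,
                                 constants = ballast_reference()$constants) {
  if (any(biovolume < 0)) abort("biovolume must be non-negative")
  biovolume * constants$si_pmol_per_um3 * constants$si_pg_per_pmol
}

#' @export
print.ballast_reference <- function(x, ...) {
  cat("Particle mass reference\n")
  cat("  coccolith taxa: ", nrow(x$coccoliths),
      " (", paste0(x$coccoliths$taxon, " ", x$coccoliths$lith_mass_pg, "pg",
                   collapse = ", "), ")\n", sep = "")
  cat("  diatom particles:", nrow(x$diatoms), "\n")
  cat("  aliases:", paste(names(x$aliases), "->", x$aliases, collapse = "; "), "\n")
  cat("  silica conversion:", x$constants$si_pmol_per_um3, "pmol/um^3 x",
      x$constants$si_pg_per_pmol, "pg/pmol =",
      x$constants$si_pmol_per_um3 * x$constants$si_pg_per_pmol, "pg/um^3\n")
  cat("  lorica dry weight:", x$constants$lorica_dry_weight_pg, "+/-",
      x$constants$lorica_dry_weight_sd_pg, "pg\n")
  invisible(x)
}
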