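## Packaged literature ledgers.
##
## The four published per-lorica/assemblage tables ship as CSV fixtures.
## Encoding rules: a coccolith cell printed in pg that is an exact multiple of
## the default per-lith mass is stored as a lith count (e.g. 880 pg of
## Emiliania -> 220 liths x 4 pg); otherwise it is stored verbatim as
## `mass_pg`. Diatom cells are stored as printed (pg silica). Printed summary
## rows with no per-lorica breakdown (group means) are stored as group-mean
## pseudo-loricae with `n_loricae` > 1. "x of n" occurrence cells become
## occurrence annotations, never invented per-lorica observations. Printed
## row totals whose components do not reproduce them are listed in
## [known_discrepancies()] and kept as printed in `printed_total_pg`.

FIXTURE_NAMES <- c("table2", "table3_atlantic", "table3_sots", "table4", "table5")

#' Load a packaged literature ledger
#'
#' @param name one of `"table2"` (Codonellopsis cf. soyai, Kerguelen Plateau,
#'   11 loricae, per-lorica), `"table3_atlantic"` (Codonellopsis pusilla,
#'   North Atlantic, four printed type-groups, n = 35), `"table3_sots"`
#'   (C. pusilla, Southern Ocean Time Series, one group, n = 13), `"table4"`
#'   (Codonella galea, Tonga + Coral Sea, per-lorica) or `"table5"`
#'   (Dictyocysta lepida, three regional groups plus the printed pooled
#'   tropical value).
#' @param reference a [ballast_reference()].
#' @return a validated [lorica_ledger()].
#' @export
#' @examples
#' load_fixture("table2")
load_fixture <- function(name, reference = ballast_reference()) {
  if (!name %in% FIXTURE_NAMES)
    abort("unknown fixture ", sq(name), "; available: ",
          paste(FIXTURE_NAMES, collapse = ", "))
  dir <- system.file("extdata", "fixtures", name, package = "loricaballast",
                     mustWork = TRUE)
  led <- read_ledger(dir, reference = reference)
  led$source <- name
  led
}

#' Known discrepancies in the printed source tables
#'
#' Printed row totals that their own printed components do not reproduce
#' (beyond +/- 1 pg after integer rounding). Both the printed and the
#' recomputed value are retained; neither is silently "fixed". Tests assert
#' recomputed totals against `recomputed_total_pg` for these rows and against
#' `printed_total_pg` for all others.
#'
#' @return data.frame with columns `fixture`, `lorica_id`, `printed_total_pg`,
#'   `recomputed_total_pg`, `note`.
#' @export
known_discrepancies <- function() {
  f <- system.file("extdata", "fixtures", "known_discrepancies.csv",
                   package = "loricaballast", mustWork = TRUE)
  read.csv(f, stringsAsFactors = FALSE)
}
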