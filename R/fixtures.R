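# Built-in 19F resonance-set fixtures.
#
# Chemical shifts follow the usual 19F referencing (CFCl3 = 0 ppm), so
# the PFAS fingerprint region is negative.  Shift catalogues emulate the
# compound classes seen in environmental and biological screening:
# trifluoroacetic acid (TFA, -77 ppm), inorganic fluoride (-121.4 ppm),
# aromatic trifluoromethyl compounds (-61.5 .. -68.1 ppm), the CF2 next
# to a fluorotelomer alcohol group (-113.4 ppm), and the diagnostic CF2
# resonances next to the polar head group: PFCAs (-118.7), PFSAs
# (-117.9), sulfonamides (-117.7, -117.2) and fluorotelomer species
# (-116.6, -115.5 ppm).  Amplitudes, relaxation times and noise are
# user-set; the fixtures are synthetic stand-ins for the corresponding
# sample types, not measured data.

fixture_catalogue <- function() {
  list(
    tap_water_like = list(
      description = paste(
        "Synthetic drinking-water-like set: inorganic fluoride, TFA,",
        "PFCA resonances and four aromatic-CF3 compounds."),
      table = data.frame(
        label = c("fluoride", "TFA", "PFCA_CF3", "PFCA_CF2",
                  "aromatic_CF3_a", "aromatic_CF3_b", "aromatic_CF3_c",
                  "aromatic_CF3_d"),
        ppm = c(-121.4, -77, -82, -119, -61.5, -62.4, -63.8, -68.1),
        n_fluorine = c(1, 3, 3, 2, 3, 3, 3, 3),
        stringsAsFactors = FALSE)),
    polar_bear_liver_like = list(
      description = paste(
        "Synthetic polar-bear-liver-like set: TFA, the diagnostic CF2",
        "resonances of PFCAs, PFSAs, sulfonamides and fluorotelomer",
        "species, and two aromatic-CF3 compounds."),
      table = data.frame(
        label = c("TFA", "PFCA_CF2", "PFSA_CF2", "sulfonamide_CF2_a",
                  "sulfonamide_CF2_b", "fluorotelomer_CF2_a",
                  "fluorotelomer_CF2_b", "aromatic_CF3_a",
                  "aromatic_CF3_b"),
        ppm = c(-77, -118.7, -117.9, -117.7, -117.2, -116.6, -115.5,
                -63.8, -64.6),
        n_fluorine = c(3, 2, 2, 2, 2, 2, 2, 3, 3),
        stringsAsFactors = FALSE)),
    six_compound_standard = list(
      description = paste(
        "Synthetic six-compound quantification standard with well",
        "separated shifts spanning the common 19F functional-group",
        "regions; TFA serves as the internal standard."),
      table = data.frame(
        label = c("aromatic_CF3", "TFA", "alkyl_CF3", "FTOH_CF2",
                  "PFSA_CF2", "PFCA_CF2"),
        ppm = c(-62.4, -77, -81.1, -113.4, -117.9, -118.7),
        n_fluorine = c(3, 3, 3, 2, 2, 2),
        stringsAsFactors = FALSE))
  )
}

#' Built-in 19F PFAS fixture sets
#'
#' Returns a named resonance catalogue with configurable amplitudes and
#' relaxation defaults.  Available fixtures: \code{"tap_water_like"},
#' \code{"polar_bear_liver_like"}, \code{"six_compound_standard"} (all
#' synthetic).
#'
#' @param name fixture name.
#' @param amplitude_per_f amplitude per equivalent fluorine nucleus; each
#'   resonance gets \code{amplitude_per_f * n_fluorine}.  A vector of
#'   per-resonance amplitudes (overriding the per-fluorine scaling) may
#'   be given instead via \code{amplitudes}.
#' @param amplitudes optional explicit per-resonance amplitudes.
#' @param t1_s,t2_s relaxation defaults applied to every resonance.
#' @param decay_rate optional explicit decay rates; default
#'   \code{1/t2_s} (T2* equal to T2, no extra inhomogeneity broadening).
#' @return an object of class \code{"pfas_fixture"}: \code{name},
#'   \code{description}, and a \code{table} of labels, ppm values and
#'   per-resonance parameters.  Use \code{\link{fixture_resonances}} to
#'   resolve it against an acquisition grid.
#' @export
pfas_fixture <- function(name, amplitude_per_f = 1, amplitudes = NULL,
                         t1_s = 1.2, t2_s = 0.6, decay_rate = NULL) {
  cat_ <- fixture_catalogue()
  if (!is.character(name) || length(name) != 1L || !name %in% names(cat_))
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; catalogue: ", paste(names(cat_), collapse = ", "))
  fx <- cat_[[name]]
  tab <- fx$table
  tab$amplitude <- if (is.null(amplitudes))
    amplitude_per_f * tab$n_fluorine else rep_len(amplitudes, nrow(tab))
  tab$t1_s <- t1_s
  tab$t2_s <- t2_s
  tab$decay_rate <- if (is.null(decay_rate)) 1 / tab$t2_s else
    rep_len(decay_rate, nrow(tab))
  structure(list(name = name, description = fx$description, table = tab),
            class = "pfas_fixture")
}

#' @export
print.pfas_fixture <- function(x, ...) {
  cat("Fixture '", x$name, "': ", x$description, "\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Resolve a fixture against an acquisition grid
#'
#' Converts the fixture's ppm values to frequency offsets for the given
#' observe frequency and carrier, and returns a ready-to-simulate
#' \code{\link{resonance_set}}.  Resonances outside the grid's spectral
#' width are an error.
#'
#' @param fixture a \code{\link{pfas_fixture}}.
#' @param grid an \code{acq_grid}.
#' @param phase_rad phase applied to every resonance (default 0).
#' @return a \code{resonance_set}.
#' @export
fixture_resonances <- function(fixture, grid, phase_rad = 0) {
  stopifnot(inherits(fixture, "pfas_fixture"), inherits(grid, "acq_grid"))
  f <- ppm_to_hz(grid, fixture$table$ppm)
  sw <- spectral_width(grid)
  if (any(abs(f) > sw / 2))
    stop("fixture resonances at ",
         paste(round(fixture$table$ppm[abs(f) > sw / 2], 1), collapse = ", "),
         " ppm fall outside the spectral width; widen the grid or move ",
         "the carrier")
  resonance_set(frequency_hz = f, amplitude = fixture$table$amplitude,
                decay_rate = fixture$table$decay_rate,
                phase_rad = phase_rad, t1_s = fixture$table$t1_s,
                t2_s = fixture$table$t2_s,
                n_fluorine = fixture$table$n_fluorine,
                label = fixture$table$label)
}
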