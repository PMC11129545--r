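# Embedded atomic-physics tables and the polychromatic source-spectrum model.
#
# Tables live in inst/extdata as versioned CSV fixtures:
#   xray_k_params.csv     element, Z, atomic mass, K edge (keV), fluorescence
#                         yield omega_K, K absorption-jump factor
#   xray_k_lines.csv      K emission lines (Ka1, Ka2, Kb1) with energies and
#                         intensities relative to Ka1 = 100
#   mass_attenuation.csv  per-element energy grid with photoelectric,
#                         incoherent (Compton), coherent (Rayleigh) and total
#                         mass attenuation coefficients, cm^2/g

.xfet <- new.env(parent = emptyenv())

.load_tables <- function() {
  if (!is.null(.xfet$kpar)) return(invisible())
  path <- function(f) system.file("extdata", f, package = "xfetring", mustWork = TRUE)
  .xfet$kpar <- utils::read.csv(path("xray_k_params.csv"), stringsAsFactors = FALSE)
  .xfet$lines <- utils::read.csv(path("xray_k_lines.csv"), stringsAsFactors = FALSE)
  mu <- utils::read.csv(path("mass_attenuation.csv"), stringsAsFactors = FALSE)
  .xfet$mu <- split(mu, mu$element)
  invisible()
}

.kpar_row <- function(element) {
  .load_tables()
  i <- match(element, .xfet$kpar$element)
  if (is.na(i))
    stop("element '", element, "' is not in the embedded physics tables", call. = FALSE)
  .xfet$kpar[i, ]
}

#' K emission line table
#'
#' @return data frame of the embedded K lines (element, line label, energy in
#'   keV, intensity relative to Kalpha1 = 100).
#' @export
xray_lines <- function() {
  .load_tables()
  .xfet$lines
}

#' Intensity-weighted K line energy
#'
#' Returns the intensity-weighted mean energy of an element's Kalpha
#' (Ka1 + Ka2) or Kbeta emission, in keV.  These are the photopeak positions
#' used for XRF imaging windows.
#'
#' @param element element symbol, e.g. `"Gd"`.
#' @param label `"Ka"` or `"Kb"`.
#' @export
line_energy <- function(element, label = c("Ka", "Kb")) {
  label <- match.arg(label)
  .load_tables()
  ln <- .xfet$lines[.xfet$lines$element == element, ]
  if (nrow(ln) == 0)
    stop("no emission lines tabulated for element '", element, "'", call. = FALSE)
  sel <- if (label == "Ka") ln$line %in% c("Ka1", "Ka2") else ln$line %in% c("Kb1")
  ln <- ln[sel, ]
  sum(ln$energy_kev * ln$rel_intensity) / sum(ln$rel_intensity)
}

#' K-shell binding energy (K edge), keV
#' @param element element symbol.
#' @export
k_edge <- function(element) .kpar_row(element)$k_edge

#' K fluorescence yield omega_K
#' @param element element symbol.
#' @export
fluorescence_yield <- function(element) .kpar_row(element)$fluor_yield

#' K absorption-jump factor
#' @param element element symbol.
#' @export
jump_factor <- function(element) .kpar_row(element)$jump

#' Fraction of K emission in the Kalpha lines
#' @param element element symbol.
#' @export
kalpha_fraction <- function(element) {
  .load_tables()
  ln <- .xfet$lines[.xfet$lines$element == element, ]
  if (nrow(ln) == 0)
    stop("no emission lines tabulated for element '", element, "'", call. = FALSE)
  ka <- sum(ln$rel_intensity[ln$line %in% c("Ka1", "Ka2")])
  ka / sum(ln$rel_intensity)
}

## ---- materials --------------------------------------------------------------

#' Material mixture
#'
#' A material is a set of elemental mass fractions plus a bulk density.
#' Fractions must be nonnegative and are renormalized to sum to one (an error
#' is raised if they are further than 1e-6 from unity before renormalization).
#'
#' @param fractions named numeric vector of elemental mass fractions.
#' @param density bulk density, g/cm^3.
#' @param name optional label.
#' @export
xfet_material <- function(fractions, density, name = NULL) {
  stopifnot(is.numeric(fractions), !is.null(names(fractions)), density > 0)
  if (any(fractions < 0)) stop("mass fractions must be nonnegative", call. = FALSE)
  s <- sum(fractions)
  if (abs(s - 1) > 1e-6)
    stop("mass fractions must sum to 1 (got ", signif(s, 6), ")", call. = FALSE)
  structure(list(fractions = fractions / s, density = density,
                 name = if (is.null(name)) "material" else name),
            class = "xfet_material")
}

#' @export
print.xfet_material <- function(x, ...) {
  cat("<xfet_material>", x$name, " rho =", x$density, "g/cm^3\n")
  print(round(x$fractions, 4)); invisible(x)
}

#' Standard materials
#'
#' Water; acrylic modeled as PMMA (C5O2H8, 1.18 g/cm^3); tube walls as
#' PTFE (C2F4, 2.2 g/cm^3); CdTe detector substrate (5.85 g/cm^3); beryllium
#' exit window (1.848 g/cm^3).
#'
#' @param name one of `"water"`, `"pmma"`, `"ptfe"`, `"cdte"`, `"be"`.
#' @export
standard_material <- function(name = c("water", "pmma", "ptfe", "cdte", "be")) {
  name <- match.arg(name)
  switch(name,
    water = xfet_material(c(H = 2 * 1.008, O = 15.999) / (2 * 1.008 + 15.999),
                          1.0, "water"),
    pmma = {
      m <- c(C = 5 * 12.011, O = 2 * 15.999, H = 8 * 1.008)
      xfet_material(m / sum(m), 1.18, "pmma")
    },
    ptfe = {
      m <- c(C = 2 * 12.011, F = 4 * 18.998)
      xfet_material(m / sum(m), 2.2, "ptfe")
    },
    cdte = {
      m <- c(Cd = 112.414, Te = 127.60)
      xfet_material(m / sum(m), 5.85, "cdte")
    },
    be = xfet_material(c(Be = 1), 1.848, "beryllium"))
}

#' Dilute aqueous solution of a metal solute
#'
#' Water plus `mg_per_ml` milligrams of `solute` per milliliter; in the dilute
#' limit used throughout (<= 6 mg/mL) the density is taken as that of water
#' plus the solute mass.
#'
#' @param solutes named numeric vector, mg/mL per element (may be empty).
#' @export
solution_material <- function(solutes = numeric()) {
  if (any(solutes < 0)) stop("concentrations must be nonnegative", call. = FALSE)
  rho <- 1.0 + sum(solutes) / 1000
  wf <- solutes / 1000 / rho                       # solute mass fractions
  w <- standard_material("water")$fractions * (1 - sum(wf))
  fr <- tapply(c(w, wf), names(c(w, wf)), sum)
  fr <- stats::setNames(as.numeric(fr), names(fr))
  m <- xfet_material(fr, density = rho,
                     name = if (length(solutes))
                       paste0("water+", paste(names(solutes), unname(solutes),
                                              sep = ":", collapse = ","))
                     else "water")
  m$solutes <- solutes
  m
}

## ---- attenuation ------------------------------------------------------------

.elem_mu <- function(element, energy, component) {
  .load_tables()
  tb <- .xfet$mu[[element]]
  if (is.null(tb))
    stop("element '", element, "' is not in the attenuation table", call. = FALSE)
  if (any(energy < min(tb$energy_kev) | energy > max(tb$energy_kev)))
    stop("energy outside the tabulated grid [",
         signif(min(tb$energy_kev), 4), ", ", signif(max(tb$energy_kev), 4),
         "] keV for ", element, call. = FALSE)
  # log-log interpolation; the K edge is represented by two grid points a
  # numerical epsilon apart, so interpolation never crosses the discontinuity
  exp(stats::approx(log(tb$energy_kev), log(tb[[component]]), xout = log(energy),
                    ties = "ordered")$y)
}

#' Mass attenuation coefficient of a material or element
#'
#' Mixture rule: mass-fraction-weighted sum of elemental coefficients,
#' log-log interpolated on the embedded grid (never across a K edge).
#'
#' @param material an [xfet_material] or an element symbol.
#' @param energy photon energies, keV (vectorized).
#' @param component one of `"total"`, `"photoelectric"`, `"incoherent"`,
#'   `"coherent"`.
#' @return coefficients in cm^2/g.
#' @export
mass_attenuation <- function(material, energy,
                             component = c("total", "photoelectric",
                                           "incoherent", "coherent")) {
  component <- match.arg(component)
  if (is.character(material))
    return(.elem_mu(material, energy, component))
  stopifnot(inherits(material, "xfet_material"))
  out <- numeric(length(energy))
  for (e in names(material$fractions)) {
    f <- material$fractions[[e]]
    if (f > 0) out <- out + f * .elem_mu(e, energy, component)
  }
  out
}

#' Linear attenuation coefficient, 1/cm
#' @inheritParams mass_attenuation
#' @export
linear_attenuation <- function(material, energy, component = "total")
  mass_attenuation(material, energy, component) * material$density

#' Photoelectric cross-section ratio just above the K edges
#'
#' Ratio of the photoelectric mass attenuation coefficients of two elements,
#' each evaluated in the limit from above at its own K edge.  This is the
#' quantity that controls the relative XRF excitation efficiency per unit
#' (mass) concentration of two contrast elements.
#'
#' @param element_a,element_b element symbols.
#' @export
photoelectric_edge_ratio <- function(element_a, element_b) {
  v <- vapply(c(element_a, element_b), function(e) {
    edge <- k_edge(e)
    .elem_mu(e, edge + 1e-3, "photoelectric")
  }, numeric(1))
  unname(v[1] / v[2])
}

## ---- source spectrum --------------------------------------------------------

#' Polychromatic X-ray tube spectrum
#'
#' Analytic model of an X-ray tube spectrum: Kramers bremsstrahlung continuum
#' (photon fluence per unit energy proportional to Z (kVp - E)/E), plus the
#' anode's characteristic K lines whenever the accelerating potential exceeds
#' the anode K edge, filtered by the exit window, and normalized to unit total
#' fluence.
#'
#' The characteristic-to-continuum balance is a configurable parameter
#' `char_fraction` (fraction of total exit fluence carried by the anode K
#' lines, before normalization bookkeeping); the default reproduces the
#' spectral character of a reflection-target Mo tube in which the majority of
#' the emitted beam energy lies below 21 keV.
#'
#' @param kvp accelerating potential, kV (> 0).
#' @param anode anode element symbol (default molybdenum).
#' @param window_material window material (an [xfet_material]); default
#'   beryllium.
#' @param window_um window thickness in micrometers (default 254).
#' @param bin_width energy bin width, keV (default 0.1).
#' @param char_fraction fraction of the exit fluence in the anode
#'   characteristic lines (0 disables them; ignored when kVp is below the
#'   anode K edge).
#' @return an object of class `beam_spectrum`: data frame with bin edges,
#'   centers and relative fluence per bin (summing to 1), plus metadata.
#' @export
source_spectrum <- function(kvp = 90, anode = "Mo",
                            window_material = standard_material("be"),
                            window_um = 254, bin_width = 0.1,
                            char_fraction = 0.45) {
  if (kvp <= 0) stop("kvp must be positive", call. = FALSE)
  lo <- 1
  edges <- seq(lo, kvp, by = bin_width)
  if (edges[length(edges)] < kvp) edges <- c(edges, kvp)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  dE <- diff(edges)
  zan <- .kpar_row(anode)$z
  cont <- zan * (kvp - mid) / mid * dE
  # window transmission
  tw <- exp(-mass_attenuation(window_material, mid) *
              window_material$density * window_um * 1e-4)
  cont <- cont * tw
  fl <- cont
  if (kvp > k_edge(anode) && char_fraction > 0) {
    ln <- .xfet$lines[.xfet$lines$element == anode, ]
    amp <- ln$rel_intensity / sum(ln$rel_intensity)
    twl <- exp(-mass_attenuation(window_material, ln$energy_kev) *
                 window_material$density * window_um * 1e-4)
    # lines carry char_fraction of the total exit fluence
    w <- amp * twl
    w <- w / sum(w) * char_fraction / (1 - char_fraction) * sum(cont)
    for (i in seq_len(nrow(ln))) {
      j <- findInterval(ln$energy_kev[i], edges, rightmost.closed = TRUE)
      fl[j] <- fl[j] + w[i]
    }
  }
  fl <- fl / sum(fl)
  structure(list(edges = edges, energy_kev = mid, fluence = fl,
                 kvp = kvp, anode = anode,
                 window = list(material = window_material$name,
                               thickness_um = window_um)),
            class = "beam_spectrum")
}

#' @export
print.beam_spectrum <- function(x, ...) {
  cat("<beam_spectrum>", x$kvp, "kVp", x$anode, "anode,",
      length(x$energy_kev), "bins, window", x$window$material,
      x$window$thickness_um, "um\n")
  cat("  mean energy", round(sum(x$energy_kev * x$fluence), 2), "keV\n")
  invisible(x)
}

#' Fraction of beam fluence above an energy
#'
#' Fraction of the spectrum's photon fluence carried by bins whose center lies
#' above `energy`.  Energies outside the spectrum support clamp to 0 or 1.
#'
#' @param spectrum a `beam_spectrum`.
#' @param energy threshold, keV.
#' @export
spectrum_fraction_above <- function(spectrum, energy) {
  stopifnot(inherits(spectrum, "beam_spectrum"))
  vapply(energy, function(e) sum(spectrum$fluence[spectrum$energy_kev > e]),
         numeric(1))
}

#' Fraction of beam *energy* below a threshold
#' @inheritParams spectrum_fraction_above
#' @export
spectrum_energy_fraction_below <- function(spectrum, energy) {
  en <- spectrum$energy_kev * spectrum$fluence
  sum(en[spectrum$energy_kev < energy]) / sum(en)
}

#' Write / read a spectrum as two-column CSV (bin center keV, relative fluence)
#' @param spectrum a `beam_spectrum`.
#' @param file path.
#' @export
write_spectrum_csv <- function(spectrum, file) {
  utils::write.csv(data.frame(energy_kev = spectrum$energy_kev,
                              fluence = spectrum$fluence),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(file) {
  d <- utils::read.csv(file)
  stopifnot(all(c("energy_kev", "fluence") %in% names(d)))
  dE <- diff(d$energy_kev)
  dE <- c(dE, dE[length(dE)])
  edges <- c(d$energy_kev - dE / 2, d$energy_kev[nrow(d)] + dE[length(dE)] / 2)
  structure(list(edges = edges, energy_kev = d$energy_kev,
                 fluence = d$fluence / sum(d$fluence),
                 kvp = max(d$energy_kev), anode = NA_character_,
                 window = list(material = NA_character_, thickness_um = NA_real_)),
            class = "beam_spectrum")
}
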