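# Shared fixtures, built once per test run.

.fx <- new.env()

fx_geometry <- function() {
  if (is.null(.fx$geom)) .fx$geom <- xfet_geometry()
  .fx$geom
}

fx_spectrum <- function() {
  if (is.null(.fx$spec)) .fx$spec <- source_spectrum()
  .fx$spec
}

fx_booklet <- function() {
  if (is.null(.fx$booklet))
    .fx$booklet <- read.csv(test_path("ref_xray_booklet.csv"),
                            stringsAsFactors = FALSE)
  .fx$booklet
}

# brute-force all-pairs CSD oracle: keep an event iff no other event in the
# same (frame, module) is within Chebyshev distance 1
csd_brute_force <- function(events) {
  keep <- rep(TRUE, nrow(events))
  if (nrow(events) < 2) return(events)
  key <- paste(events$frame, events$module)
  for (g in split(seq_len(nrow(events)), key)) {
    if (length(g) < 2) next
    for (i in g) {
      others <- setdiff(g, i)
      d <- pmax(abs(events$row[others] - events$row[i]),
                abs(events$col[others] - events$col[i]))
      if (any(d <= 1)) keep[i] <- FALSE
    }
  }
  events[keep, , drop = FALSE]
}

# solute concentration of an element in a fill material (0 when absent)
conc_of <- function(fill, element) {
  s <- fill$solutes
  if (is.null(s) || !(element %in% names(s))) 0 else unname(s[[element]])
}

# random list-mode frame generator for CSD tests
random_events <- function(n, n_frames, pix = 20, seed) {
  set.seed(seed)
  data.frame(frame = sample.int(n_frames, n, replace = TRUE) - 1L,
             module = sample(0:3, n, replace = TRUE),
             row = sample.int(pix, n, replace = TRUE) - 1L,
             col = sample.int(pix, n, replace = TRUE) - 1L,
             energy_kev = runif(n, 5, 100))
}
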