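## Internal helpers shared across modules.

RACES <- c("caucasian", "african", "chinese")
START_POSITIONS <- c("left", "right", "up", "down")
AOI_NAMES <- c("left_eye", "bridge", "right_eye",
               "nose_left", "nose_right", "mouth_left", "mouth_right")
AOI_GROUPS <- c("left_eye", "bridge", "right_eye", "nose", "mouth", "other")

rect <- function(x0, y0, x1, y1) {
  r <- c(x0 = unname(x0), y0 = unname(y0), x1 = unname(x1), y1 = unname(y1))
  if (!all(is.finite(r))) stop("rectangle coordinates must be finite")
  if (r["x0"] >= r["x1"] || r["y0"] >= r["y1"])
    stop("degenerate rectangle: need x0 < x1 and y0 < y1")
  r
}

rect_center <- function(r) {
  c(x = unname((r["x0"] + r["x1"]) / 2), y = unname((r["y0"] + r["y1"]) / 2))
}

# half-open membership (vectorised over x, y)
rect_contains <- function(r, x, y) {
  x >= r["x0"] & x < r["x1"] & y >= r["y0"] & y < r["y1"]
}

rect_inside <- function(inner, outer) {
  inner["x0"] >= outer["x0"] && inner["x1"] <= outer["x1"] &&
    inner["y0"] >= outer["y0"] && inner["y1"] <= outer["y1"]
}

# open-interval overlap; touching edges do not overlap under the half-open
# convention
rects_overlap <- function(a, b) {
  a["x0"] < b["x1"] && b["x0"] < a["x1"] &&
    a["y0"] < b["y1"] && b["y0"] < a["y1"]
}

shift_rect <- function(r, dx, dy) {
  rect(r["x0"] + dx, r["y0"] + dy, r["x1"] + dx, r["y1"] + dy)
}

# Evaluate expr with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Counter-scheme seed derivation: independent substreams (iterations, stages)
# are seeded by a documented affine map of the master seed so that the order
# in which substreams are consumed does not matter.
derive_seed <- function(seed, counter) {
  (as.numeric(seed) * 48271 + as.numeric(counter) * 16807) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}
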