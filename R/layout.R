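#' Face layout: AOI rectangles for one face stimulus
#'
#' A face layout records, in degrees of visual angle, the rectangular image
#' frame of one face stimulus and seven rectangular areas of interest (AOIs):
#' `left_eye`, `bridge`, `right_eye`, `nose_left`, `nose_right`, `mouth_left`
#' and `mouth_right`. The nose and mouth halves arise by simple bisection of
#' the full nose/mouth rectangle in the x dimension, so each pair shares a
#' common vertical edge. Rectangles are half-open (a point on a shared edge
#' belongs to exactly one rectangle), must lie within the frame, and must be
#' mutually non-overlapping.
#'
#' @param face_id Character identifier, unique within a dataset.
#' @param race One of `"caucasian"`, `"african"`, `"chinese"`.
#' @param frame Numeric `c(x0, y0, x1, y1)` image frame in degrees.
#' @param aois Named list of seven numeric `c(x0, y0, x1, y1)` rectangles.
#'
#' @return An object of class `gc_layout`.
#' @export
#' @examples
#' lay <- template_face_layout("f1", "caucasian")
#' aoi_centers(lay)
face_layout <- function(face_id, race, frame, aois) {
  race <- match.arg(race, RACES)
  frame <- rect(frame[1], frame[2], frame[3], frame[4])
  if (!is.list(aois) || !setequal(names(aois), AOI_NAMES))
    stop("`aois` must be a named list with exactly the AOIs: ",
         paste(AOI_NAMES, collapse = ", "))
  aois <- lapply(aois[AOI_NAMES], function(r) rect(r[1], r[2], r[3], r[4]))
  obj <- structure(list(face_id = as.character(face_id), race = race,
                        frame = frame, aois = aois),
                   class = "gc_layout")
  validate_layout(obj)
  obj
}

validate_layout <- function(layout) {
  aois <- layout$aois
  for (nm in AOI_NAMES) {
    if (!rect_inside(aois[[nm]], layout$frame))
      stop(sprintf("AOI '%s' of face '%s' extends outside the frame",
                   nm, layout$face_id))
  }
  nms <- AOI_NAMES
  for (i in seq_along(nms)[-length(nms)]) {
    for (j in seq.int(i + 1L, length(nms))) {
      if (rects_overlap(aois[[nms[i]]], aois[[nms[j]]]))
        stop(sprintf("AOIs '%s' and '%s' of face '%s' overlap",
                     nms[i], nms[j], layout$face_id))
    }
  }
  shared_edge <- function(l, r, what) {
    if (abs(aois[[l]]["x1"] - aois[[r]]["x0"]) > 1e-9 ||
        abs(aois[[l]]["y0"] - aois[[r]]["y0"]) > 1e-9 ||
        abs(aois[[l]]["y1"] - aois[[r]]["y1"]) > 1e-9)
      stop(sprintf("%s halves of face '%s' are not a simple x bisection",
                   what, layout$face_id))
  }
  shared_edge("nose_left", "nose_right", "nose")
  shared_edge("mouth_left", "mouth_right", "mouth")
  invisible(layout)
}

#' @export
print.gc_layout <- function(x, ...) {
  cat(sprintf("<gc_layout> face '%s' (%s), frame [%g, %g] x [%g, %g], 7 AOIs\n",
              x$face_id, x$race, x$frame["x0"], x$frame["x1"],
              x$frame["y0"], x$frame["y1"]))
  invisible(x)
}

#' AOI centers of a face layout
#'
#' @param layout A `gc_layout`.
#' @return A 7 x 2 matrix of AOI center coordinates (columns `x`, `y`),
#'   rows named by AOI.
#' @export
aoi_centers <- function(layout) {
  m <- t(vapply(layout$aois, rect_center, numeric(2)))
  colnames(m) <- c("x", "y")
  m
}

#' Template face layout
#'
#' The canonical face geometry used by the synthetic-data generator: a face
#' with a forehead width of 10 degrees of visual angle centered in an
#' 11 x 13 degree image frame, eyes and bridge in the upper third, nose in
#' the middle, mouth in the lower third. Per-face geometric variability is
#' produced by jittering this template (see [generate_face_layouts()]).
#'
#' @param face_id,race Passed through to [face_layout()].
#' @return A `gc_layout`.
#' @export
template_face_layout <- function(face_id = "template", race = "caucasian") {
  face_layout(
    face_id, race,
    frame = c(2.5, 1.5, 13.5, 14.5),
    aois = list(
      left_eye   = c(4.7, 5.2, 7.0, 6.7),
      bridge     = c(7.4, 5.2, 8.6, 6.7),
      right_eye  = c(9.0, 5.2, 11.3, 6.7),
      nose_left  = c(6.7, 7.1, 8.0, 9.0),
      nose_right = c(8.0, 7.1, 9.3, 9.0),
      mouth_left = c(6.3, 9.4, 8.0, 10.9),
      mouth_right = c(8.0, 9.4, 9.7, 10.9)
    )
  )
}

#' Mirror a face layout about the vertical midline of its frame
#'
#' Emulates left-right flipping of a face stimulus: every rectangle is
#' reflected about the frame's vertical midline and the left/right AOI names
#' are swapped so that, e.g., `left_eye` still denotes the AOI on the
#' viewer's left.
#'
#' @param layout A `gc_layout`.
#' @return The mirrored `gc_layout`.
#' @export
mirror_layout <- function(layout) {
  mid <- unname(layout$frame["x0"] + layout$frame["x1"])
  flip <- function(r) rect(mid - r["x1"], r["y0"], mid - r["x0"], r["y1"])
  a <- layout$aois
  swapped <- list(
    left_eye = flip(a$right_eye), bridge = flip(a$bridge),
    right_eye = flip(a$left_eye),
    nose_left = flip(a$nose_right), nose_right = flip(a$nose_left),
    mouth_left = flip(a$mouth_right), mouth_right = flip(a$mouth_left)
  )
  face_layout(layout$face_id, layout$race,
              layout$frame[c("x0", "y0", "x1", "y1")], swapped)
}

#' Read and write AOI definition tables
#'
#' The AOI table is a UTF-8 tab-separated file with columns `face_id`,
#' `race`, `aoi_name`, `x0_deg`, `y0_deg`, `x1_deg`, `y1_deg`. Each face
#' contributes one row per AOI plus one row with the reserved `aoi_name`
#' `"frame"` giving the image frame. All layout invariants are enforced on
#' read; duplicate `(face_id, aoi_name)` pairs are an error.
#'
#' @param path File path.
#' @return `read_aois()` returns a named list of `gc_layout` objects.
#' @export
read_aois <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    stringsAsFactors = FALSE)
  need <- c("face_id", "race", "aoi_name", "x0_deg", "y0_deg", "x1_deg", "y1_deg")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("AOI table is missing column(s): ", paste(miss, collapse = ", "))
  for (cc in c("x0_deg", "y0_deg", "x1_deg", "y1_deg")) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- which(is.na(v) & nzchar(tab[[cc]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data line %d", cc, bad[1]))
    tab[[cc]] <- v
  }
  if (anyDuplicated(tab[c("face_id", "aoi_name")]))
    stop("duplicate (face_id, aoi_name) row in AOI table")
  layouts <- lapply(split(tab, tab$face_id), function(d) {
    fr <- d[d$aoi_name == "frame", ]
    if (nrow(fr) != 1L)
      stop("face '", d$face_id[1], "' must have exactly one 'frame' row")
    ao <- d[d$aoi_name != "frame", ]
    if (!setequal(ao$aoi_name, AOI_NAMES))
      stop("face '", d$face_id[1], "' does not define exactly the 7 AOIs")
    aois <- lapply(seq_len(nrow(ao)), function(i)
      c(ao$x0_deg[i], ao$y0_deg[i], ao$x1_deg[i], ao$y1_deg[i]))
    names(aois) <- ao$aoi_name
    face_layout(d$face_id[1], d$race[1],
                c(fr$x0_deg, fr$y0_deg, fr$x1_deg, fr$y1_deg), aois)
  })
  layouts[order(names(layouts))]
}

#' @rdname read_aois
#' @param layouts Named list of `gc_layout` objects.
#' @export
write_aois <- function(layouts, path) {
  rows <- lapply(layouts, function(l) {
    rs <- c(list(frame = l$frame), l$aois)
    data.frame(face_id = l$face_id, race = l$race,
               aoi_name = c("frame", AOI_NAMES),
               x0_deg = vapply(rs, `[[`, 0, "x0"),
               y0_deg = vapply(rs, `[[`, 0, "y0"),
               x1_deg = vapply(rs, `[[`, 0, "x1"),
               y1_deg = vapply(rs, `[[`, 0, "y1"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$face_id, match(tab$aoi_name, c("frame", AOI_NAMES))), ]
  write.table(format_num_df(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# format numeric columns with 17 significant digits and '.' separator,
# so that write -> read round-trips are value-exact for doubles
format_num_df <- function(d) {
  for (cc in names(d)) {
    if (is.numeric(d[[cc]])) {
      v <- formatC(d[[cc]], format = "g", digits = 17)
      v[is.na(d[[cc]])] <- ""
      d[[cc]] <- trimws(v)
    }
  }
  d
}
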