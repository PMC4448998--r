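# Anchor-based normalization of developmental time.
#
# Recordings are aligned onto a common 0-100 axis through four annotated
# morphological events: first blastomeres (0), gastrulation (10), ventral
# enclosure (43) and the 2-fold tail stage (54). Between anchors the mapping
# is piecewise linear; beyond the last anchor it extrapolates with the final
# segment's slope and is capped at 100.

#' Anchor event annotations (wall-clock seconds)
#'
#' @param t_start appearance of ABa (or EMS) - normalized time 0.
#' @param t_gast gastrulation - normalized time 10.
#' @param t_venc ventral enclosure - normalized time 43.
#' @param t_2ftail 2-fold tail stage - normalized time 54.
#' @return an object of class `anchor_annotations`.
#' @export
anchor_annotations <- function(t_start, t_gast, t_venc, t_2ftail) {
  t <- c(t_start, t_gast, t_venc, t_2ftail)
  if (any(!is.finite(t)) || any(diff(t) <= 0))
    stop_input("anchor times must be finite and strictly increasing")
  structure(list(t_start = t_start, t_gast = t_gast,
                 t_venc = t_venc, t_2ftail = t_2ftail),
            class = "anchor_annotations")
}

#' Default normalized values of the four anchors
#'
#' @return named numeric: start 0, gast 10, venc 43, 2ftail 54, and the
#'   terminal cap 100 (a hard cap, not an anchor with a wall-clock time).
#' @export
time_anchor_defaults <- function() {
  c(start = 0, gast = 10, venc = 43, `2ftail` = 54, terminal = 100)
}

#' Map wall-clock time to normalized developmental time
#'
#' Piecewise-linear interpolation through the four anchors, exact at each
#' anchor. Beyond the last anchor the final segment's slope is reused and
#' the result is capped at 100; before the first anchor the first segment's
#' slope extrapolates (possibly to negative values, which are flagged via
#' the `"extrapolated"` attribute together with capped times).
#'
#' @param anchors an [anchor_annotations()].
#' @param t wall-clock time(s) in seconds.
#' @param defaults normalized anchor values (see [time_anchor_defaults()]).
#' @param cap cap the result at the terminal value (default TRUE).
#' @return normalized time(s), with attribute `extrapolated` marking entries
#'   outside the anchored span.
#' @examples
#' a <- anchor_annotations(0, 600, 3000, 4200)
#' map_time(a, 3000)           # 43
#' map_time(a, (600 + 3000)/2) # 26.5
#' @export
map_time <- function(anchors, t, defaults = time_anchor_defaults(),
                     cap = TRUE) {
  tw <- c(anchors$t_start, anchors$t_gast, anchors$t_venc, anchors$t_2ftail)
  tn <- unname(defaults[c("start", "gast", "venc", "2ftail")])
  terminal <- unname(defaults["terminal"])
  out <- numeric(length(t))
  seg <- findInterval(t, tw, rightmost.closed = FALSE, all.inside = TRUE)
  slope <- diff(tn) / diff(tw)
  out <- tn[seg] + (t - tw[seg]) * slope[seg]
  extrap <- t < tw[1] | out > terminal
  if (cap) out <- pmin(out, terminal)
  attr(out, "extrapolated") <- extrap
  out
}

#' Attach normalized time to a calibrated series
#'
#' Applies [map_time()] to every stack timestamp. Stacks whose uncapped
#' normalized time exceeds 100 are truncated: the mapping ends when the
#' normalized time reaches 100 or the recording ends.
#'
#' @param series a [reconstruct_series()] result.
#' @param anchors an [anchor_annotations()].
#' @param defaults normalized anchor values.
#' @return the series with `info$time_norm` filled and late stacks dropped.
#' @export
normalize_recording <- function(series, anchors,
                                defaults = time_anchor_defaults()) {
  raw <- map_time(anchors, series$info$time_s, defaults, cap = FALSE)
  inside <- series$info$time_s >= anchors$t_start &
    series$info$time_s <= anchors$t_2ftail
  if (sum(c(anchors$t_start, anchors$t_gast, anchors$t_venc,
            anchors$t_2ftail) >= min(series$info$time_s) &
          c(anchors$t_start, anchors$t_gast, anchors$t_venc,
            anchors$t_2ftail) <= max(series$info$time_s)) < 2)
    warning("fewer than two anchors inside the recording span; pure extrapolation")
  keep <- raw <= unname(defaults["terminal"])
  series$volumes <- series$volumes[keep]
  series$info <- series$info[keep, , drop = FALSE]
  series$info$time_norm <- as.numeric(raw[keep])
  rownames(series$info) <- NULL
  series
}

#' Per-cell linear time maps from an annotated lineage
#'
#' When a recording carries an annotated lineage, time is normalized per
#' cell: each annotated cell's (birth, death) wall-clock interval is mapped
#' linearly onto the model cell's (birth, death) normalized interval.
#'
#' @param annotation data frame with columns `name`, `birth_s`, `death_s`.
#' @param model a [generate_reference_model()] object.
#' @return named list of functions mapping wall-clock seconds to normalized
#'   time, one per annotated cell; each carries `slope` and `intercept`
#'   attributes.
#' @export
map_time_per_cell <- function(annotation, model) {
  unknown <- setdiff(annotation$name, model$cells$name)
  if (length(unknown))
    stop_input("cells absent from the model: ",
               paste(unknown, collapse = ", "))
  maps <- lapply(seq_len(nrow(annotation)), function(i) {
    nm <- annotation$name[i]
    b_w <- annotation$birth_s[i]; d_w <- annotation$death_s[i]
    b_m <- model$cells[nm, "birth"]; d_m <- model$cells[nm, "death"]
    if (d_w <= b_w) stop_input("cell ", nm, ": death before birth")
    slope <- (d_m - b_m) / (d_w - b_w)
    intercept <- b_m - slope * b_w
    f <- function(t) intercept + slope * t
    attr(f, "slope") <- slope
    attr(f, "intercept") <- intercept
    f
  })
  names(maps) <- annotation$name
  maps
}
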