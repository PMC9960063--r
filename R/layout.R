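# Dynamic page layout: components, AOI groupings, scroll and pop-up state.
#
# Components live either in page coordinates (they move with scroll) or, when
# sticky, in viewport coordinates (the menu bar follows the screen). One AOI
# may be a pop-up that, while open, occludes everything underneath: during a
# pop-up interval only the pop-up rectangle can be hit, all other AOIs are
# deactivated.

#' Construct an AOI layout
#'
#' @param screen `c(width, height)` of the viewport in pixels.
#' @param components Data frame with columns `id`, `x0`, `y0`, `x1`, `y1`,
#'   `sticky`. Rectangles are half-open (`x0 <= x < x1`). Sticky rectangles
#'   are in viewport coordinates, others in page coordinates. Components must
#'   not overlap within the same (sticky or page) layer.
#' @param aois List of AOI definitions: each a list with `index` (1..n),
#'   `components` (character vector of member ids), `dynamic` and
#'   `occludes_below` flags. Component sets of distinct AOIs must be disjoint;
#'   components in no AOI count as whitespace for labelling.
#' @return An object of class `aoi_layout`.
#' @export
aoi_layout <- function(screen, components, aois) {
  stopifnot(length(screen) == 2, all(screen > 0))
  need <- c("id", "x0", "y0", "x1", "y1", "sticky")
  if (!all(need %in% names(components))) {
    stop("components must have columns ", paste(need, collapse = ", "))
  }
  components <- components[need]
  components$id <- as.character(components$id)
  if (anyDuplicated(components$id)) stop("duplicate component ids")
  if (any(components$x0 >= components$x1) || any(components$y0 >= components$y1)) {
    stop("component rectangles must satisfy x0 < x1, y0 < y1")
  }
  for (layer in split(components, components$sticky)) {
    n <- nrow(layer)
    if (n > 1) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (layer$x0[i] < layer$x1[j] && layer$x0[j] < layer$x1[i] &&
            layer$y0[i] < layer$y1[j] && layer$y0[j] < layer$y1[i]) {
          stop("components overlap within a layer: ",
               layer$id[i], " / ", layer$id[j])
        }
      }
    }
  }
  idx <- vapply(aois, function(a) as.integer(a$index), integer(1))
  if (!identical(sort(idx), seq_along(aois))) stop("AOI indexes must be 1..n")
  aois <- aois[order(idx)]
  members <- unlist(lapply(aois, `[[`, "components"))
  if (anyDuplicated(members)) stop("AOI component sets must be disjoint")
  if (!all(members %in% components$id)) {
    stop("AOI references unknown components: ",
         paste(setdiff(members, components$id), collapse = ", "))
  }
  popup_idx <- which(vapply(aois, function(a) isTRUE(a$occludes_below), logical(1)))
  if (length(popup_idx) > 1) stop("at most one AOI may occlude below (the pop-up)")
  # component -> AOI index lookup (NA = whitespace / ungrouped)
  aoi_of <- setNames(rep(NA_integer_, nrow(components)), components$id)
  for (a in aois) aoi_of[a$components] <- as.integer(a$index)
  structure(list(
    screen = as.numeric(screen),
    components = components,
    aois = aois,
    n_aoi = length(aois),
    aoi_of = aoi_of,
    popup_aoi = if (length(popup_idx)) as.integer(popup_idx) else NA_integer_
  ), class = "aoi_layout")
}

#' @export
print.aoi_layout <- function(x, ...) {
  cat(sprintf("<aoi_layout> %dx%d px, %d components, %d AOIs%s\n",
              x$screen[1], x$screen[2], nrow(x$components), x$n_aoi,
              if (!is.na(x$popup_aoi))
                sprintf(" (AOI %d is an occluding pop-up)", x$popup_aoi)
              else ""))
  invisible(x)
}

#' Read / write a layout as JSON
#'
#' Format: `{"screen":[w,h],"components":[{"id","rect","sticky"}],
#' "aois":[{"index","components","dynamic","occludes_below"}]}` with `rect`
#' as `[x0,y0,x1,y1]`.
#'
#' @param path JSON file path.
#' @return `read_layout()` returns an `aoi_layout`.
#' @export
read_layout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  comps <- do.call(rbind, lapply(j$components, function(cp) {
    r <- unlist(cp$rect)
    data.frame(id = cp$id, x0 = r[1], y0 = r[2], x1 = r[3], y1 = r[4],
               sticky = isTRUE(cp$sticky))
  }))
  aois <- lapply(j$aois, function(a) list(
    index = a$index, components = unlist(a$components),
    dynamic = isTRUE(a$dynamic), occludes_below = isTRUE(a$occludes_below)))
  aoi_layout(unlist(j$screen), comps, aois)
}

#' @rdname read_layout
#' @param layout An `aoi_layout`.
#' @export
write_layout <- function(layout, path) {
  comps <- lapply(seq_len(nrow(layout$components)), function(i) {
    cp <- layout$components[i, ]
    list(id = cp$id, rect = c(cp$x0, cp$y0, cp$x1, cp$y1), sticky = cp$sticky)
  })
  jsonlite::write_json(
    list(screen = layout$screen, components = comps, aois = layout$aois),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build the dynamic layout state from interaction events
#'
#' The scroll offset is a right-continuous step function of time built from
#' `scroll` events (payload = new vertical offset in page pixels; an optional
#' `"dx:dy"` payload sets both offsets). Pop-up intervals are `[open, close)`
#' spans from paired `popup_open` / `popup_close` events; an unclosed pop-up
#' extends to `duration_ms`.
#'
#' @param events Event data frame (`t_ms`, `kind`, `payload`).
#' @param duration_ms Recording span, closes any dangling pop-up.
#' @return An object of class `layout_state`.
#' @export
layout_state <- function(events = NULL, duration_ms = Inf) {
  if (is.null(events) || !nrow(events)) {
    events <- data.frame(t_ms = numeric(0), kind = character(0),
                         payload = character(0))
  }
  events <- events[order(events$t_ms), , drop = FALSE]
  sc <- events[events$kind == "scroll", , drop = FALSE]
  off <- t(vapply(sc$payload, function(p) {
    v <- suppressWarnings(as.numeric(strsplit(as.character(p), ":", fixed = TRUE)[[1]]))
    if (any(is.na(v))) stop("bad scroll payload: ", p)
    if (length(v) == 1) c(0, v) else v[1:2]
  }, numeric(2)))
  if (!nrow(sc)) off <- matrix(numeric(0), ncol = 2)
  if (any(off < 0)) stop("scroll offsets must be >= 0")
  opens <- events$t_ms[events$kind == "popup_open"]
  closes <- events$t_ms[events$kind == "popup_close"]
  if (length(closes) > length(opens)) stop("popup_close without popup_open")
  intervals <- cbind(open = opens,
                     close = c(closes, rep(duration_ms,
                                           length(opens) - length(closes))))
  if (nrow(intervals) > 1 &&
      any(intervals[-1, "open"] < intervals[-nrow(intervals), "close"])) {
    stop("pop-up intervals must not overlap")
  }
  structure(list(
    scroll_t = sc$t_ms, scroll_dx = off[, 1], scroll_dy = off[, 2],
    popup = intervals
  ), class = "layout_state")
}

#' Scroll offset at given times
#'
#' Step function: the offset set by the latest scroll event at or before `t`;
#' `(0, 0)` before the first event.
#'
#' @param state A `layout_state`.
#' @param t Time(s) in ms.
#' @return A matrix with columns `dx`, `dy`, one row per time.
#' @export
scroll_offset <- function(state, t) {
  i <- findInterval(t, state$scroll_t)
  cbind(dx = ifelse(i == 0, 0, state$scroll_dx[pmax(i, 1)]),
        dy = ifelse(i == 0, 0, state$scroll_dy[pmax(i, 1)]))
}

popup_open_at <- function(state, t) {
  if (!nrow(state$popup)) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (r in seq_len(nrow(state$popup))) {
    out <- out | (t >= state$popup[r, "open"] & t < state$popup[r, "close"])
  }
  out
}

#' Map screen coordinates to page coordinates
#'
#' Page point = screen point + scroll offset at `t`. Sticky components are
#' hit-tested in screen space, so this conversion applies only to the
#' page-fixed layer.
#'
#' @param xy Length-2 vector or 2-column matrix of screen coordinates.
#' @param state A `layout_state`.
#' @param t Time(s) in ms.
#' @return Matrix of page coordinates.
#' @export
to_page_point <- function(xy, state, t) {
  xy <- rbind_xy(xy)
  off <- scroll_offset(state, t)
  cbind(x = xy[, 1] + off[, "dx"], y = xy[, 2] + off[, "dy"])
}

rbind_xy <- function(xy) {
  if (is.null(dim(xy))) matrix(xy, ncol = 2) else as.matrix(xy)
}

# half-open rectangle containment against one layer of components;
# returns component row index or 0
rect_hit <- function(comps, x, y) {
  hit <- integer(length(x))
  if (!nrow(comps)) return(hit)
  for (i in seq_len(nrow(comps))) {
    inside <- x >= comps$x0[i] & x < comps$x1[i] &
              y >= comps$y0[i] & y < comps$y1[i]
    hit[inside & hit == 0L] <- i
  }
  hit
}

#' Hit-test gaze points against the dynamic layout
#'
#' Total function: every point resolves to a component (or `"whitespace"`)
#' and an AOI index (or `NA`). While a pop-up interval covers `t`, points
#' inside the pop-up rectangle resolve to the pop-up AOI and every other
#' point to whitespace (the underlying AOIs are deactivated). Otherwise the
#' sticky layer is tested first in screen space, then the page layer in page
#' space (screen + scroll offset).
#'
#' @param xy Screen coordinates, length-2 vector or 2-column matrix.
#' @param t Time(s) in ms, recycled to the number of points.
#' @param layout An `aoi_layout`.
#' @param state A `layout_state` (defaults to the static state).
#' @return Data frame with columns `component` (character) and `aoi`
#'   (integer, `NA` for whitespace/ungrouped).
#' @export
hit_test <- function(xy, t, layout, state = layout_state()) {
  xy <- rbind_xy(xy)
  n <- nrow(xy)
  t <- rep_len(t, n)
  comp <- rep("whitespace", n)
  aoi <- rep(NA_integer_, n)
  comps <- layout$components
  popup_open <- popup_open_at(state, t)

  if (any(popup_open) && !is.na(layout$popup_aoi)) {
    pids <- layout$aois[[layout$popup_aoi]]$components
    prect <- comps[comps$id %in% pids, , drop = FALSE]
    sel <- which(popup_open)
    h <- rect_hit(prect, xy[sel, 1], xy[sel, 2])
    comp[sel[h > 0]] <- prect$id[h[h > 0]]
    aoi[sel[h > 0]] <- layout$popup_aoi
  }
  sel <- which(!popup_open)
  if (length(sel)) {
    # pop-up components never hit while closed
    closed_ids <- if (!is.na(layout$popup_aoi))
      layout$aois[[layout$popup_aoi]]$components else character(0)
    sticky <- comps[comps$sticky & !(comps$id %in% closed_ids), , drop = FALSE]
    h <- rect_hit(sticky, xy[sel, 1], xy[sel, 2])
    done <- h > 0
    comp[sel[done]] <- sticky$id[h[done]]
    aoi[sel[done]] <- unname(layout$aoi_of[sticky$id[h[done]]])
    rest <- sel[!done]
    if (length(rest)) {
      page <- to_page_point(xy[rest, , drop = FALSE], state, t[rest])
      fixed <- comps[!comps$sticky & !(comps$id %in% closed_ids), , drop = FALSE]
      h <- rect_hit(fixed, page[, 1], page[, 2])
      comp[rest[h > 0]] <- fixed$id[h[h > 0]]
      aoi[rest[h > 0]] <- unname(layout$aoi_of[fixed$id[h[h > 0]]])
    }
  }
  data.frame(component = comp, aoi = aoi, stringsAsFactors = FALSE)
}
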