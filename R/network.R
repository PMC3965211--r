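# Microtubule network geometry.
#
# A microtubule is a directed 2-D segment from its minus end to its plus end;
# the arc coordinate runs from 0 at the minus end to `length` at the plus end.
# A network is the set of microtubules plus every interior pairwise crossing,
# each stored with both arc coordinates and the crossing point.

#' Build a microtubule network from endpoint pairs
#'
#' @param segments list of microtubules, each a list/vector pair
#'   `(minus_end, plus_end)` of 2-D points in um, or a 2x2 matrix with rows
#'   minus end / plus end.
#' @return An object of class `mt_network` with components `mts` (data frame
#'   `mt_id, minus_x_um, minus_y_um, plus_x_um, plus_y_um, length_um`) and
#'   `intersections` (data frame `int_id, mt_a, mt_b, arc_a_um, arc_b_um,
#'   x_um, y_um`; every interior pairwise crossing exactly once).
#' @details Zero-length microtubules are rejected as invalid geometry and
#'   collinear overlapping pairs as unsupported geometry (they have no single
#'   crossing point).
#' @export
build_network <- function(segments) {
  if (length(segments) < 1) stop("need at least one microtubule segment")
  mts <- do.call(rbind, lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    if (is.matrix(s)) s <- list(s[1, ], s[2, ])
    m <- as.numeric(s[[1]]); p <- as.numeric(s[[2]])
    if (length(m) != 2 || length(p) != 2 || !all(is.finite(c(m, p)))) {
      stop("invalid geometry: endpoints must be finite 2-D points")
    }
    len <- sqrt(sum((p - m)^2))
    if (len <= 0) stop("invalid geometry: zero-length microtubule (segment ",
                       i, ")")
    data.frame(mt_id = i, minus_x_um = m[1], minus_y_um = m[2],
               plus_x_um = p[1], plus_y_um = p[2], length_um = len)
  }))

  ints <- list()
  n <- nrow(mts)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        hit <- segment_crossing(
          c(mts$minus_x_um[i], mts$minus_y_um[i]),
          c(mts$plus_x_um[i], mts$plus_y_um[i]),
          c(mts$minus_x_um[j], mts$minus_y_um[j]),
          c(mts$plus_x_um[j], mts$plus_y_um[j]))
        if (is.character(hit)) {
          stop("unsupported geometry: collinear overlapping microtubules (",
               i, ", ", j, ")")
        }
        if (!is.null(hit)) {
          ints[[length(ints) + 1]] <- data.frame(
            mt_a = i, mt_b = j,
            arc_a_um = hit["ta"] * mts$length_um[i],
            arc_b_um = hit["tb"] * mts$length_um[j],
            x_um = hit["x"], y_um = hit["y"])
        }
      }
    }
  }
  intersections <- if (length(ints)) {
    out <- do.call(rbind, ints)
    rownames(out) <- NULL
    cbind(int_id = seq_len(nrow(out)), out)
  } else {
    data.frame(int_id = integer(), mt_a = integer(), mt_b = integer(),
               arc_a_um = numeric(), arc_b_um = numeric(),
               x_um = numeric(), y_um = numeric())
  }
  structure(list(mts = mts, intersections = intersections),
            class = "mt_network")
}

# Interior crossing of segments p1-p2 and q1-q2 by the parametric solve.
# Returns NULL (no interior crossing), a named vector (ta, tb, x, y), or the
# string "overlap" for collinear overlapping segments.
segment_crossing <- function(p1, p2, q1, q2, eps = 1e-9) {
  r <- p2 - p1
  s <- q2 - q1
  denom <- r[1] * s[2] - r[2] * s[1]
  qp <- q1 - p1
  if (abs(denom) < eps * sqrt(sum(r^2)) * sqrt(sum(s^2))) {
    # parallel; collinear if qp is parallel to r as well
    cross_qp <- qp[1] * r[2] - qp[2] * r[1]
    if (abs(cross_qp) < eps * max(1, sqrt(sum(r^2)))) {
      # collinear: overlap test via projections onto r
      t0 <- sum(qp * r) / sum(r * r)
      t1 <- t0 + sum(s * r) / sum(r * r)
      if (max(min(t0, t1), 0) <= min(max(t0, t1), 1) + eps) return("overlap")
    }
    return(NULL)
  }
  ta <- (qp[1] * s[2] - qp[2] * s[1]) / denom
  tb <- (qp[1] * r[2] - qp[2] * r[1]) / denom
  if (ta <= eps || ta >= 1 - eps || tb <= eps || tb >= 1 - eps) return(NULL)
  xy <- p1 + ta * r
  c(ta = ta, tb = tb, x = xy[1], y = xy[2])
}

#' @export
print.mt_network <- function(x, ...) {
  cat(sprintf("Microtubule network: %d microtubules, %d intersections\n",
              nrow(x$mts), nrow(x$intersections)))
  invisible(x)
}

#' Length of a microtubule in a network
#' @param network an `mt_network`.
#' @param mt_id microtubule id (vectorised).
#' @return length, um.
#' @export
mt_length <- function(network, mt_id) {
  network$mts$length_um[match(mt_id, network$mts$mt_id)]
}

#' Map (microtubule, arc position) to xy coordinates
#' @param network an `mt_network`.
#' @param mt_id microtubule ids (vectorised).
#' @param arc_um arc positions from the minus end, um.
#' @return two-column matrix `x_um, y_um`.
#' @export
arc_to_xy <- function(network, mt_id, arc_um) {
  i <- match(mt_id, network$mts$mt_id)
  f <- arc_um / network$mts$length_um[i]
  cbind(x_um = network$mts$minus_x_um[i] +
          f * (network$mts$plus_x_um[i] - network$mts$minus_x_um[i]),
        y_um = network$mts$minus_y_um[i] +
          f * (network$mts$plus_y_um[i] - network$mts$minus_y_um[i]))
}

# Intersections that live on a given microtubule: data frame with the arc
# position on that microtubule and the partner microtubule/arc.
intersections_on_mt <- function(network, mt_id) {
  ii <- network$intersections
  a <- ii[ii$mt_a == mt_id, c("int_id", "arc_a_um", "mt_b", "arc_b_um")]
  names(a) <- c("int_id", "arc_um", "other_mt", "other_arc_um")
  b <- ii[ii$mt_b == mt_id, c("int_id", "arc_b_um", "mt_a", "arc_a_um")]
  names(b) <- c("int_id", "arc_um", "other_mt", "other_arc_um")
  out <- rbind(a, b)
  out[order(out$arc_um), , drop = FALSE]
}
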