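#' Polygon gate on two descriptor axes
#'
#' @param name gate (and cluster) label.
#' @param x_axis,y_axis descriptor column names (e.g. `"total_FWS"`,
#'   `"max_FLR"`, `"ratio_FLO_SWS"`).
#' @param vertices numeric matrix (>= 3 rows, columns x, y) of a simple
#'   polygon, in axis units *after* scaling.
#' @param x_scale,y_scale `"log10"` or `"linear"`.
#' @param priority integer; when an event falls in several gates, the gate
#'   with the lowest priority wins.
#' @return a `cyto_gate`.
#' @export
gate <- function(name, x_axis, y_axis, vertices, x_scale = "log10",
                 y_scale = "log10", priority = 1L) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3 || ncol(vertices) != 2) {
    stop("gate polygon needs >= 3 (x, y) vertices", call. = FALSE)
  }
  if (.polygon_self_intersects(vertices)) {
    stop("gate '", name, "' polygon is self-intersecting", call. = FALSE)
  }
  structure(list(name = name, x_axis = x_axis, y_axis = y_axis,
                 vertices = unname(vertices), x_scale = x_scale,
                 y_scale = y_scale, priority = as.integer(priority)),
            class = "cyto_gate")
}

# brute-force segment intersection check (polygons are tiny)
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), ])
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  inter <- function(p, q) {
    d1 <- cross(q[3] - q[1], q[4] - q[2], p[1] - q[1], p[2] - q[2])
    d2 <- cross(q[3] - q[1], q[4] - q[2], p[3] - q[1], p[4] - q[2])
    d3 <- cross(p[3] - p[1], p[4] - p[2], q[1] - p[1], q[2] - p[2])
    d4 <- cross(p[3] - p[1], p[4] - p[2], q[3] - p[1], q[4] - p[2])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (n <= 3) return(FALSE)
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next  # adjacent via wrap
      if (inter(seg[i, ], seg[j, ])) return(TRUE)
    }
  }
  FALSE
}

#' Gating scheme: ordered gates plus the cluster roster
#'
#' @param gates list of [gate()]s with unique names.
#' @param protocol_id optional protocol the scheme was drawn on.
#' @return a `gating_scheme` with gates sorted by priority.
#' @export
gating_scheme <- function(gates, protocol_id = NULL) {
  nms <- vapply(gates, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("gate names must be unique", call. = FALSE)
  ord <- order(vapply(gates, `[[`, 1L, "priority"))
  structure(list(gates = gates[ord], protocol_id = protocol_id),
            class = "gating_scheme")
}

#' Boundary-inclusive even-odd point-in-polygon test
#'
#' @param px,py point coordinates (vectors).
#' @param vx,vy polygon vertex coordinates.
#' @return logical vector; points on an edge or vertex count as inside.
#' @export
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  eps <- 1e-12
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # boundary: collinear and within the segment's bounding box
    d <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    scale <- pmax(abs(xj - xi), abs(yj - yi), 1)
    col_ok <- abs(d) <= eps * scale * pmax(abs(px) + abs(py), 1)
    in_box <- px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
              py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
    on_edge <- on_edge | (col_ok & in_box)
    # even-odd ray crossing
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Assign every event to a cluster
#'
#' Events are tested against the gates in priority order (lowest first) with
#' a boundary-inclusive even-odd point-in-polygon rule; the first matching
#' gate labels the event, and events matching no gate are `"Unassigned"`.
#' Events presenting a non-positive value on a log-scaled axis (or an
#' undefined FLO/SWS ratio) cannot be tested against that gate; if no gate
#' matches they end up `Unassigned`, with the number of such exclusions
#' returned in the `n_unscalable` attribute.
#'
#' @param desc descriptor table ([compute_descriptors()]).
#' @param scheme a [gating_scheme()].
#' @return character vector of labels (one per row of `desc`) with attribute
#'   `n_unscalable`.
#' @export
assign_clusters <- function(desc, scheme) {
  stopifnot(inherits(scheme, "gating_scheme"))
  n <- nrow(desc)
  labels <- rep("Unassigned", n)
  unassigned <- rep(TRUE, n)
  n_unscalable <- 0L
  for (g in scheme$gates) {
    for (ax in c(g$x_axis, g$y_axis)) {
      if (!ax %in% names(desc)) {
        stop("descriptor table lacks axis ", ax, " needed by gate ", g$name,
             call. = FALSE)
      }
    }
    x <- desc[[g$x_axis]]; y <- desc[[g$y_axis]]
    ok <- !is.na(x) & !is.na(y)
    if (g$x_scale == "log10") { ok <- ok & x > 0 }
    if (g$y_scale == "log10") { ok <- ok & y > 0 }
    n_unscalable <- n_unscalable + sum(!ok & unassigned)
    xs <- ifelse(ok, if (g$x_scale == "log10") suppressWarnings(log10(x)) else x, NA_real_)
    ys <- ifelse(ok, if (g$y_scale == "log10") suppressWarnings(log10(y)) else y, NA_real_)
    hit <- unassigned & ok &
      point_in_polygon(xs, ys, g$vertices[, 1], g$vertices[, 2])
    hit[is.na(hit)] <- FALSE
    labels[hit] <- g$name
    unassigned <- unassigned & !hit
  }
  attr(labels, "n_unscalable") <- n_unscalable
  labels
}

.rect <- function(x0, x1, y0, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

#' Default gating scheme for the synthetic optics
#'
#' Rectangular gates in log10 descriptor space calibrated to the default
#' cluster signatures: the ratio- and scatter-specific gates (PicoFLO on
#' max FWS vs the max FLO / max SWS ratio; HighSWS on max SWS vs max FLR;
#' HighFLO on total FWS vs total FLO) take precedence over the size-based
#' total FLR vs total FWS gates that separate picoeukaryotes, nano- and
#' microphytoplankton. Users gating other data supply their own scheme
#' (see [read_gating_scheme()]).
#'
#' @return a `gating_scheme`.
#' @export
default_gating_scheme <- function() {
  gating_scheme(list(
    gate("PicoFLO", "max_FWS", "ratio_FLO_SWS",
         .rect(0.40, 1.60, 0.50, 2.20), priority = 1L),
    gate("HighSWS", "max_SWS", "max_FLR",
         .rect(2.90, 4.00, 1.50, 2.70), priority = 2L),
    gate("HighFLO", "total_FWS", "total_FLO",
         .rect(2.90, 4.10, 3.20, 4.40), priority = 3L),
    gate("Picoeukaryotes", "total_FWS", "total_FLR",
         .rect(1.35, 2.45, 0.70, 1.80), priority = 4L),
    gate("Nanophytoplankton", "total_FWS", "total_FLR",
         .rect(2.60, 3.80, 2.60, 3.80), priority = 5L),
    gate("Microphytoplankton", "total_FWS", "total_FLR",
         .rect(4.00, 5.20, 3.60, 4.80), priority = 6L)
  ))
}

#' Read / write a gating scheme as YAML
#'
#' @param path YAML file path.
#' @return `read_gating_scheme()` returns a `gating_scheme`.
#' @export
read_gating_scheme <- function(path) {
  spec <- yaml::read_yaml(path)
  gates <- lapply(spec$gates, function(g) {
    gate(g$name, g$x_axis, g$y_axis,
         matrix(unlist(g$vertices), ncol = 2, byrow = TRUE),
         x_scale = g$x_scale %||% "log10", y_scale = g$y_scale %||% "log10",
         priority = g$priority)
  })
  gating_scheme(gates, protocol_id = spec$protocol_id)
}

#' @rdname read_gating_scheme
#' @param scheme a `gating_scheme`.
#' @export
write_gating_scheme <- function(scheme, path) {
  spec <- list(protocol_id = scheme$protocol_id,
               gates = lapply(scheme$gates, function(g) {
                 list(name = g$name, x_axis = g$x_axis, y_axis = g$y_axis,
                      x_scale = g$x_scale, y_scale = g$y_scale,
                      priority = g$priority,
                      vertices = lapply(seq_len(nrow(g$vertices)),
                                        function(i) as.numeric(g$vertices[i, ])))
               }))
  yaml::write_yaml(spec, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build per-cluster abundance / mean-FWS time series from a sample directory
#'
#' Reads every listmode sample under `dir`, computes descriptors, applies
#' each sample's own acquisition trigger, gates the events, and converts
#' counts to concentrations via the analysed volume. The two smallest
#' clusters (PicoFLO, Picoeukaryotes) are taken from the low-trigger
#' protocol 1; the four larger clusters from protocol 2. Gap ticks are
#' simply absent (not zero-filled).
#'
#' @param dir directory holding `events_*.csv` / `meta_*.json` pairs.
#' @param scheme a [gating_scheme()].
#' @param protocol_map named integer vector: which protocol serves each
#'   cluster.
#' @return named list of data frames (class `cluster_series`), one per
#'   mapped cluster: `time`, `abundance`, `mean_fws`, `count`, `volume_cm3`.
#' @export
cluster_abundance_series <- function(dir, scheme,
                                     protocol_map = default_protocol_map()) {
  files <- sort(list.files(dir, pattern = "^events_.*\\.csv$", full.names = TRUE))
  if (length(files) == 0) stop("no listmode samples under ", dir, call. = FALSE)
  rows <- vector("list", length(files))
  for (i in seq_along(files)) {
    smp <- read_listmode(files[i])
    vol <- analyzed_volume(smp$meta)
    if (vol <= 0) { warning("skipping zero-volume sample ", files[i]); next }
    desc <- compute_descriptors(smp)
    desc <- apply_trigger(desc, smp$meta$trigger_channel, smp$meta$trigger_level_mV)
    labels <- assign_clusters(desc, scheme)
    dt <- data.table::data.table(cluster = labels, fws = desc$total_FWS)
    agg <- dt[, .(count = .N, mean_fws = mean(fws)), by = cluster]
    agg[, `:=`(time = smp$meta$timestamp, protocol = smp$meta$protocol_id,
               volume_cm3 = vol)]
    rows[[i]] <- agg
  }
  all <- data.table::rbindlist(rows[!vapply(rows, is.null, TRUE)])
  out <- list()
  for (nm in names(protocol_map)) {
    sub <- all[cluster == nm & protocol == protocol_map[[nm]]]
    data.table::setorder(sub, time)
    # ticks where the cluster had zero gated events still exist as samples;
    # reinsert them with count 0 from the sample inventory
    inv <- all[protocol == protocol_map[[nm]],
               .(volume_cm3 = volume_cm3[1]), by = time]
    merged <- merge(inv, sub[, .(time, count, mean_fws)], by = "time",
                    all.x = TRUE)
    merged[is.na(count), count := 0L]
    df <- data.frame(time = merged$time,
                     abundance = merged$count / merged$volume_cm3,
                     mean_fws = merged$mean_fws, count = merged$count,
                     volume_cm3 = merged$volume_cm3)
    df <- df[order(df$time), ]
    rownames(df) <- NULL
    class(df) <- c("cluster_series", "data.frame")
    attr(df, "cluster") <- nm
    out[[nm]] <- df
  }
  out
}

#' @rdname cluster_abundance_series
#' @export
default_protocol_map <- function() {
  c(PicoFLO = 1L, Picoeukaryotes = 1L, Nanophytoplankton = 2L,
    Microphytoplankton = 2L, HighSWS = 2L, HighFLO = 2L)
}
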