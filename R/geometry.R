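#' Geometry of the bicellular tight-junction strand lattice
#'
#' Defines the dimensions of the 2D brick lattice used by both the molecular
#' permeability and the TER model: `n_strand` horizontal strands enclose
#' `n_strand - 1` rows of small compartments, with vertical strand sections
#' connecting the horizontal strands in a staggered (brick) pattern.
#'
#' @param n_strand Number of horizontal strands (at least 2).
#' @param width Number of compartments across the modelled strip.
#' @param w_comp Compartment width in metres.
#' @param h_comp Compartment height in metres.
#' @param w_TJ Tight-junction half-width (slit half-height for hindered
#'   diffusion) in metres.
#' @param h_strand Height of a single strand in metres.
#' @param l_break Size of a strand break in metres. Must be smaller than the
#'   shortest strand section (`w_comp / 2`) and than `h_comp`.
#' @param h_apical,h_basal Heights of the apical and basal compartments in
#'   metres. Pure bookkeeping values: they do not affect permeability or TER.
#'
#' @return An object of class `tj_geometry`.
#' @seealso [tj_network()]
#' @export
#' @examples
#' tj_geometry(n_strand = 3, width = 3)
tj_geometry <- function(n_strand = 4, width = 50,
                        w_comp = 100e-9, h_comp = 100e-9,
                        w_TJ = 4e-9, h_strand = 6e-9, l_break = 20e-9,
                        h_apical = 200e-9, h_basal = 200e-9) {
  if (!is.numeric(n_strand) || length(n_strand) != 1L || n_strand < 2 ||
      n_strand != round(n_strand)) {
    stop("'n_strand' must be an integer >= 2 (at least one compartment row)")
  }
  if (!is.numeric(width) || length(width) != 1L || width < 1 ||
      width != round(width)) {
    stop("'width' must be a positive integer")
  }
  lens <- c(w_comp = w_comp, h_comp = h_comp, w_TJ = w_TJ,
            h_strand = h_strand, l_break = l_break,
            h_apical = h_apical, h_basal = h_basal)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("all geometry lengths must be positive and finite")
  }
  if (l_break >= min(w_comp / 2, h_comp)) {
    stop("'l_break' must be smaller than the shortest strand section")
  }
  structure(
    list(n_strand = as.integer(n_strand), width = as.integer(width),
         w_comp = w_comp, h_comp = h_comp, w_TJ = w_TJ,
         h_strand = h_strand, l_break = l_break,
         h_apical = h_apical, h_basal = h_basal),
    class = "tj_geometry")
}

#' @export
print.tj_geometry <- function(x, ...) {
  cat("Tight-junction strand lattice geometry\n")
  cat(sprintf("  strands: %d  (%d compartment rows), width: %d compartments\n",
              x$n_strand, x$n_strand - 1L, x$width))
  cat(sprintf("  compartment: %.0f x %.0f nm, TJ half-width %.1f nm\n",
              x$w_comp * 1e9, x$h_comp * 1e9, x$w_TJ * 1e9))
  cat(sprintf("  strand height %.1f nm, break size %.0f nm\n",
              x$h_strand * 1e9, x$l_break * 1e9))
  invisible(x)
}

# Node codes used in the section table: compartments are 1..n, the basal
# reservoir is 0 and the apical compartment is -1.
TJ_BASAL <- 0L
TJ_APICAL <- -1L

#' Build the compartment/section/loop network of the strand lattice
#'
#' Constructs the brick lattice: rows of compartments alternate between
#' `width` full-width compartments (the row adjacent to the basal side) and
#' `width + 1` compartments whose two edge compartments are half width, so
#' every row spans the same model width. Horizontal strands are cut into
#' sections at each compartment interface (full interfaces of length
#' `w_comp`, staggered overlap interfaces of length `w_comp / 2`); vertical
#' sections of length `h_comp` connect same-row neighbours. The side walls
#' are sealed: there are no periodic or edge sections.
#'
#' The returned network also carries the current loops used by the TER
#' model's loop (mesh) analysis: every inner face of the planar network is a
#' triangle around the end of a vertical section, and one outer loop runs
#' from basal to apical along the right boundary and closes through the
#' voltage source.
#'
#' @param geom A [tj_geometry()] object.
#' @return An object of class `tj_network` with elements
#'   `compartments` (data frame: `id`, `row`, `x0`, `x1`, `area`),
#'   `sections` (data frame: `id`, `from`, `to`, `length`, `orientation`,
#'   `x0`, `x1`; `from`/`to` use 0 for basal and -1 for apical),
#'   `loops` (list of integer vectors of section ids; the last is the outer
#'   source loop), `loop_signs` (matching traversal signs), and `w_model`.
#' @export
#' @examples
#' net <- tj_network(tj_geometry(n_strand = 3, width = 3))
#' nrow(net$compartments)  # 7 compartments
#' length(net$loops)       # 10 inner loops + 1 outer loop
tj_network <- function(geom) {
  stopifnot(inherits(geom, "tj_geometry"))
  W <- geom$width
  R <- geom$n_strand - 1L
  w <- geom$w_comp
  h <- geom$h_comp
  w_model <- W * w

  ## compartments ----------------------------------------------------------
  comp <- list()
  id <- 0L
  for (r in seq_len(R)) {
    if (r %% 2L == 1L) {                    # full-width row (basal-adjacent)
      x0 <- (seq_len(W) - 1) * w
      x1 <- seq_len(W) * w
    } else {                                # offset row with half-width edges
      x0 <- c(0, (seq_len(W) - 0.5) * w)
      x1 <- c((seq_len(W) - 0.5) * w, w_model)
    }
    n_r <- length(x0)
    comp[[r]] <- data.frame(id = id + seq_len(n_r), row = r, x0 = x0, x1 = x1)
    id <- id + n_r
  }
  comp <- do.call(rbind, comp)
  comp$area <- (comp$x1 - comp$x0) * h
  n_comp <- nrow(comp)

  ## sections ---------------------------------------------------------------
  row_ids <- split(comp$id, comp$row)
  sec <- list()
  add <- function(from, to, length, orientation, x0, x1, strand) {
    sec[[length(sec) + 1L]] <<- data.frame(
      from = from, to = to, length = length,
      orientation = orientation, x0 = x0, x1 = x1, strand = strand)
  }
  # bottom strand: basal <-> row 1, one section per compartment
  r1 <- comp[comp$row == 1L, ]
  add(rep(TJ_BASAL, nrow(r1)), r1$id, r1$x1 - r1$x0, "horizontal", r1$x0,
      r1$x1, 1L)
  # interior strands: strand r + 1 separates rows r and r + 1
  if (R >= 2L) {
    for (r in seq_len(R - 1L)) {
      lo <- comp[comp$row == r, ]
      hi <- comp[comp$row == r + 1L, ]
      cuts <- seq(0, w_model, by = w / 2)
      mid <- (cuts[-1] + cuts[-length(cuts)]) / 2
      below <- lo$id[findInterval(mid, lo$x0)]
      above <- hi$id[findInterval(mid, hi$x0)]
      add(below, above, rep(w / 2, length(mid)), "horizontal",
          cuts[-length(cuts)], cuts[-1], r + 1L)
    }
  }
  # top strand: top row <-> apical, one section per compartment
  rt <- comp[comp$row == R, ]
  add(rt$id, rep(TJ_APICAL, nrow(rt)), rt$x1 - rt$x0, "horizontal", rt$x0,
      rt$x1, R + 1L)
  # vertical sections between same-row neighbours (strand = 0)
  for (r in seq_len(R)) {
    cr <- comp[comp$row == r, ]
    if (nrow(cr) >= 2L) {
      left <- cr$id[-nrow(cr)]
      right <- cr$id[-1L]
      add(left, right, rep(h, length(left)), "vertical", cr$x1[-nrow(cr)],
          cr$x1[-nrow(cr)], 0L)
    }
  }
  sec <- do.call(rbind, sec)
  sec$id <- seq_len(nrow(sec))
  sec <- sec[, c("id", "from", "to", "length", "orientation", "x0", "x1",
                 "strand")]

  net <- structure(
    list(geometry = geom, compartments = comp, sections = sec,
         w_model = w_model),
    class = "tj_network")
  lp <- build_loops(net)
  net$loops <- lp$loops
  net$loop_signs <- lp$signs
  net
}

# Look up the section joining nodes u and v; returns c(id, sign) where sign is
# +1 when the stored direction is u -> v.
section_between <- function(sec, u, v) {
  i <- which(sec$from == u & sec$to == v)
  if (length(i) == 1L) return(c(sec$id[i], 1))
  i <- which(sec$from == v & sec$to == u)
  if (length(i) == 1L) return(c(sec$id[i], -1))
  stop("no unique section between nodes ", u, " and ", v)
}

# Current loops for the loop analysis of Eq-15 type systems. Inner loops are
# the triangular faces at the two ends of every vertical section; the outer
# loop follows the rightmost section of every strand and closes through the
# ideal voltage source (which is not itself a section).
build_loops <- function(net) {
  comp <- net$compartments
  sec <- net$sections
  R <- max(comp$row)
  loops <- list()
  signs <- list()
  add_cycle <- function(nodes) {
    n <- length(nodes)
    ids <- integer(n); sg <- numeric(n)
    for (k in seq_len(n)) {
      e <- section_between(sec, nodes[k], nodes[k %% n + 1L])
      ids[k] <- e[1]; sg[k] <- e[2]
    }
    loops[[length(loops) + 1L]] <<- ids
    signs[[length(signs) + 1L]] <<- sg
  }
  vert <- sec[sec$orientation == "vertical", ]
  for (k in seq_len(nrow(vert))) {
    cl <- vert$from[k]; cr <- vert$to[k]
    r <- comp$row[comp$id == cl]
    xw <- vert$x0[k]
    below <- if (r == 1L) TJ_BASAL else {
      lo <- comp[comp$row == r - 1L, ]
      lo$id[lo$x0 < xw & xw < lo$x1]
    }
    above <- if (r == R) TJ_APICAL else {
      hi <- comp[comp$row == r + 1L, ]
      hi$id[hi$x0 < xw & xw < hi$x1]
    }
    add_cycle(c(below, cl, cr))
    add_cycle(c(cl, above, cr))
  }
  # outer loop: basal -> rightmost compartment of each row -> apical (source
  # branch implicit)
  right <- vapply(seq_len(R), function(r) max(comp$id[comp$row == r]), 0)
  n <- length(right)
  path <- c(TJ_BASAL, right, TJ_APICAL)
  ids <- integer(n + 1L); sg <- numeric(n + 1L)
  for (k in seq_len(n + 1L)) {
    e <- section_between(sec, path[k], path[k + 1L])
    ids[k] <- e[1]; sg[k] <- e[2]
  }
  loops[[length(loops) + 1L]] <- ids
  signs[[length(signs) + 1L]] <- sg
  list(loops = loops, signs = signs)
}

#' @export
print.tj_network <- function(x, ...) {
  cat("Tight-junction strand network\n")
  cat(sprintf("  %d compartments in %d rows, %d strand sections\n",
              nrow(x$compartments), max(x$compartments$row),
              nrow(x$sections)))
  cat(sprintf("  %d inner current loops + 1 outer source loop\n",
              length(x$loops) - 1L))
  cat(sprintf("  model width %.2f um\n", x$w_model * 1e6))
  invisible(x)
}

#' Section lengths of a strand network
#'
#' Vertical sections have length `h_comp`; full horizontal interfaces
#' `w_comp`; staggered overlap interfaces `w_comp / 2` (edge compartments of
#' offset rows give `w_comp / 2` top/bottom sections as well).
#'
#' @param network A [tj_network()].
#' @return Numeric vector of section lengths (m), in section-id order.
#' @export
tj_section_lengths <- function(network) {
  stopifnot(inherits(network, "tj_network"))
  network$sections$length
}

#' Serialize a strand network to JSON
#'
#' Writes compartments, sections and current loops in a plain JSON form for
#' inspection or as a text fixture. The geometry parameters are included so
#' the network can be rebuilt with [tj_network_from_json()].
#'
#' @param network A [tj_network()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
tj_network_to_json <- function(network, path = NULL) {
  stopifnot(inherits(network, "tj_network"))
  obj <- list(
    geometry = unclass(network$geometry),
    w_model = network$w_model,
    compartments = network$compartments,
    sections = network$sections,
    loops = network$loops,
    loop_signs = network$loop_signs)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname tj_network_to_json
#' @param json A JSON string or file path produced by [tj_network_to_json()].
#' @export
tj_network_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  geom <- do.call(tj_geometry, obj$geometry)
  tj_network(geom)
}
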