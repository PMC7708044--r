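#' Create a base-pair-resolution nanobeam design
#'
#' A nanobeam design describes a parallel bundle of DNA double helices of
#' equal length, the Holliday junctions (crossovers) that rigidly connect
#' pairs of helices at given base-pair positions, and the backbone nicks
#' within individual helices. Positions are counted in base pairs along the
#' beam axis: a junction position `p` refers to the bp boundary (node) `p`,
#' a nick position `p` to the bp element `p` (the element between nodes
#' `p - 1` and `p`). All positions must be strictly interior,
#' `0 < p < bp_per_helix`.
#'
#' @param n_helices Number of double helices in the bundle.
#' @param bp_per_helix Length of every helix in base pairs.
#' @param junctions Tibble or data frame with columns `helix_a`, `helix_b`,
#'   `pos` (1-based helix indices, `helix_a < helix_b`); may be `NULL`.
#' @param nicks Tibble or data frame with columns `helix`, `pos`; may be
#'   `NULL`.
#' @param packing Cross-section lattice, one of `"pair"`, `"honeycomb"`,
#'   `"square"`. Purely descriptive for the axial model; it determines which
#'   helix pairs are adjacent when designs are generated with
#'   [build_bundle()].
#' @param rise_per_bp Axial rise per base pair in nm (0.34 for B-DNA).
#' @param name Optional construct name carried through result tables.
#'
#' @return An object of class `nanobeam_design`: a list with the validated
#'   fields above plus `length_nm = bp_per_helix * rise_per_bp`.
#' @seealso [build_two_helix()], [build_bundle()], [design_preset()]
#' @export
#' @examples
#' d <- nanobeam_design(2, 100,
#'   junctions = tibble::tibble(helix_a = 1, helix_b = 2, pos = 50))
#' design_summary(d)
nanobeam_design <- function(n_helices, bp_per_helix, junctions = NULL,
                            nicks = NULL, packing = c("pair", "honeycomb", "square"),
                            rise_per_bp = 0.34, name = NULL) {
  n_helices <- check_scalar(n_helices, "n_helices", lower = 1, integer = TRUE)
  bp <- check_scalar(bp_per_helix, "bp_per_helix", lower = 1, integer = TRUE)
  rise_per_bp <- check_scalar(rise_per_bp, "rise_per_bp", lower = 0, strict = TRUE)
  packing <- match.arg(packing)

  junctions <- normalize_junctions(junctions, n_helices, bp)
  nicks <- normalize_nicks(nicks, n_helices, bp)

  # a nick sitting exactly on a junction node of the same helix can never be
  # assembled (its element is inside every possible junction block)
  if (nrow(nicks) > 0L && nrow(junctions) > 0L) {
    part <- junction_participations(junctions, n_helices)
    for (h in unique(nicks$helix)) {
      clash <- intersect(nicks$pos[nicks$helix == h], part[[h]])
      if (length(clash) > 0L) {
        stop_validation("Nick at position %d coincides with a junction on helix %d.",
                        clash[1L], h)
      }
    }
  }

  structure(
    list(
      name = name %||% "custom",
      n_helices = n_helices,
      bp_per_helix = bp,
      rise_per_bp = rise_per_bp,
      packing = packing,
      junctions = junctions,
      nicks = nicks,
      length_nm = bp * rise_per_bp
    ),
    class = "nanobeam_design"
  )
}

normalize_junctions <- function(junctions, n_helices, bp) {
  if (is.null(junctions) || nrow(as.data.frame(junctions)) == 0L) {
    return(tibble(helix_a = integer(), helix_b = integer(), pos = integer()))
  }
  j <- as_tibble(junctions)
  if (!all(c("helix_a", "helix_b", "pos") %in% names(j))) {
    stop_validation("`junctions` needs columns helix_a, helix_b, pos.")
  }
  j <- tibble(
    helix_a = as.integer(pmin(j$helix_a, j$helix_b)),
    helix_b = as.integer(pmax(j$helix_a, j$helix_b)),
    pos = as.integer(j$pos)
  )
  if (any(j$helix_a == j$helix_b)) {
    stop_validation("A junction must connect two distinct helices.")
  }
  if (any(j$helix_a < 1L | j$helix_b > n_helices)) {
    stop_validation("Junction helix indices must lie in 1..%d.", n_helices)
  }
  if (any(j$pos <= 0L | j$pos >= bp)) {
    stop_validation("Junction positions must be strictly interior (0 < pos < %d).", bp)
  }
  j <- dplyr::arrange(j, .data$helix_a, .data$helix_b, .data$pos)
  dup <- duplicated(j[, c("helix_a", "helix_b", "pos")])
  if (any(dup)) {
    stop_validation("Duplicate junction for pair (%d, %d) at position %d.",
                    j$helix_a[dup][1L], j$helix_b[dup][1L], j$pos[dup][1L])
  }
  j
}

normalize_nicks <- function(nicks, n_helices, bp) {
  if (is.null(nicks) || nrow(as.data.frame(nicks)) == 0L) {
    return(tibble(helix = integer(), pos = integer()))
  }
  nk <- as_tibble(nicks)
  if (!all(c("helix", "pos") %in% names(nk))) {
    stop_validation("`nicks` needs columns helix, pos.")
  }
  nk <- tibble(helix = as.integer(nk$helix), pos = as.integer(nk$pos))
  if (any(nk$helix < 1L | nk$helix > n_helices)) {
    stop_validation("Nick helix indices must lie in 1..%d.", n_helices)
  }
  if (any(nk$pos <= 0L | nk$pos >= bp)) {
    stop_validation("Nick positions must be strictly interior (0 < pos < %d).", bp)
  }
  nk <- dplyr::arrange(nk, .data$helix, .data$pos)
  if (any(duplicated(nk))) stop_validation("Duplicate nick position.")
  nk
}

# per-helix junction participation positions, as a list indexed by helix
junction_participations <- function(junctions, n_helices) {
  out <- vector("list", n_helices)
  for (h in seq_len(n_helices)) {
    out[[h]] <- sort(c(junctions$pos[junctions$helix_a == h],
                       junctions$pos[junctions$helix_b == h]))
  }
  out
}

#' Build a two-helix DX-tile nanobeam
#'
#' Constructs the canonical two-helix nanobeam: a pair of parallel duplexes
#' joined by double crossovers every `junction_spacing_bp` base pairs. A
#' junction is placed at each multiple of the spacing that leaves at least
#' half a repeat to the helix end, so a 3600 bp beam carries 170 junctions at
#' 21 bp spacing and 85 at 42 bp spacing. In the nicked (non-ligated) state
#' each helix carries one nick per junction, at the midpoint (rounded down)
#' of the interval that follows the junction, at the same axial position in
#' both helices -- 2 x n_junctions nicks in total. Ligated beams have none.
#'
#' @param bp_per_helix Helix length in base pairs (>= 1).
#' @param junction_spacing_bp Crossover spacing in base pairs (>= 2).
#' @param ligated If `TRUE`, all nicks are sealed (no nick sites).
#' @param rise_per_bp Axial rise per bp in nm.
#' @param name Optional construct name.
#' @return A [nanobeam_design()] object with `packing = "pair"`.
#' @export
#' @examples
#' design_summary(build_two_helix(3600, 21, ligated = FALSE)) # C170N topology
build_two_helix <- function(bp_per_helix, junction_spacing_bp, ligated = FALSE,
                            rise_per_bp = 0.34, name = NULL) {
  bp <- check_scalar(bp_per_helix, "bp_per_helix", lower = 1, integer = TRUE)
  s <- check_scalar(junction_spacing_bp, "junction_spacing_bp", lower = 2,
                    integer = TRUE)
  ligated <- check_flag(ligated, "ligated")

  # junction kept only if at least half a repeat remains to the end
  n_j <- max(0L, as.integer(floor((2 * bp - s) / (2 * s))))
  pos <- s * seq_len(n_j)
  junctions <- tibble(helix_a = rep(1L, n_j), helix_b = rep(2L, n_j), pos = pos)

  nicks <- NULL
  if (!ligated && n_j > 0L) {
    nxt <- c(pos[-1L], bp)
    mid <- as.integer(floor((pos + nxt) / 2))
    nicks <- tibble(helix = rep(1:2, each = n_j), pos = rep(mid, 2L))
  }

  nanobeam_design(2L, bp, junctions, nicks, packing = "pair",
                  rise_per_bp = rise_per_bp,
                  name = name %||% sprintf("two-helix/%dbp%s", s,
                                           if (ligated) "/ligated" else "/nicked"))
}

packing_interfaces <- function(n_helices, packing) {
  n <- n_helices
  if (n == 1L) return(cbind(a = integer(), b = integer()))
  if (n == 2L) return(cbind(a = 1L, b = 2L))
  switch(packing,
    pair = cbind(a = seq_len(n - 1L), b = seq_len(n - 1L) + 1L),
    honeycomb = {
      # cross-section ring: every helix has two neighbours
      a <- seq_len(n)
      b <- c(seq_len(n)[-1L], 1L)
      cbind(a = pmin(a, b), b = pmax(a, b))
    },
    square = {
      # near-square grid with 4-neighbour adjacency
      divs <- which(n %% seq_len(n) == 0)
      r <- max(divs[divs <= sqrt(n)])
      cc <- n %/% r
      g <- function(i, j) (i - 1L) * cc + j
      e <- list()
      for (i in seq_len(r)) for (j in seq_len(cc)) {
        if (j < cc) e[[length(e) + 1L]] <- c(g(i, j), g(i, j + 1L))
        if (i < r) e[[length(e) + 1L]] <- c(g(i, j), g(i + 1L, j))
      }
      m <- do.call(rbind, e)
      cbind(a = m[, 1L], b = m[, 2L])
    }
  )
}

greedy_edge_coloring <- function(edges) {
  m <- nrow(edges)
  colors <- integer(m)
  for (k in seq_len(m)) {
    adj <- which(edges[, 1L] %in% edges[k, ] | edges[, 2L] %in% edges[k, ])
    adj <- setdiff(adj, k)
    used <- colors[adj]
    colors[k] <- min(setdiff(seq_len(m + 1L), used[used > 0L]))
  }
  colors
}

#' Build an idealized multi-helix bundle
#'
#' Generates a bundle of `n_helices` parallel duplexes with junctions spread
#' uniformly over the interfaces of the packing's adjacency graph (a ring for
#' honeycomb cross-sections, a near-square grid for square packing), phase-
#' staggered between interfaces so that each helix participates in
#' `junctions_per_21bp` junctions per 21 bp (within rounding), and nicks
#' placed per helix at `nicks_per_21bp`, at midpoints between that helix's
#' junction participations.
#'
#' @param n_helices Number of helices (>= 1).
#' @param packing `"pair"`, `"honeycomb"` or `"square"`.
#' @param length_nm Beam length in nm; `bp_per_helix = round(length_nm / rise_per_bp)`.
#' @param junctions_per_21bp Junction participations per helix per 21 bp.
#' @param nicks_per_21bp Nicks per helix per 21 bp.
#' @param rise_per_bp Axial rise per bp in nm.
#' @param min_separation_bp Minimum bp separation enforced between junction
#'   participations on the same helix (matches the default 5 bp junction
#'   block of [material_params()]).
#' @param name Optional construct name.
#' @return A [nanobeam_design()] object.
#' @export
#' @examples
#' design_summary(build_bundle(6, "honeycomb", 428, 2, 0.5))
build_bundle <- function(n_helices, packing = c("honeycomb", "square", "pair"),
                         length_nm, junctions_per_21bp = 2, nicks_per_21bp = 0.5,
                         rise_per_bp = 0.34, min_separation_bp = 5L, name = NULL) {
  n <- check_scalar(n_helices, "n_helices", lower = 1, integer = TRUE)
  packing <- match.arg(packing)
  length_nm <- check_scalar(length_nm, "length_nm", lower = 0, strict = TRUE)
  j_dens <- check_scalar(junctions_per_21bp, "junctions_per_21bp", lower = 0)
  nu_dens <- check_scalar(nicks_per_21bp, "nicks_per_21bp", lower = 0)
  min_sep <- check_scalar(min_separation_bp, "min_separation_bp", lower = 1,
                          integer = TRUE)
  rise_per_bp <- check_scalar(rise_per_bp, "rise_per_bp", lower = 0, strict = TRUE)

  bp <- as.integer(round(length_nm / rise_per_bp))
  if (bp < 1L) stop_validation("length_nm = %g is shorter than one base pair.", length_nm)

  edges <- packing_interfaces(n, packing)
  target <- as.integer(round(bp * j_dens / 21))
  if (target > 0L && nrow(edges) == 0L) {
    stop_validation("%s packing of %d helix has no interfaces to carry junctions.",
                    packing, n)
  }

  junctions <- bundle_junctions(edges, n, bp, target, min_sep)
  nicks <- bundle_nicks(junctions, n, bp,
                        n_nicks = as.integer(round(bp * nu_dens / 21)),
                        min_sep = min_sep)

  nanobeam_design(n, bp, junctions, nicks, packing = packing,
                  rise_per_bp = rise_per_bp,
                  name = name %||% sprintf("%d-helix/%s", n, packing))
}

bundle_junctions <- function(edges, n, bp, target, min_sep) {
  m <- nrow(edges)
  if (target == 0L || m == 0L) {
    return(tibble(helix_a = integer(), helix_b = integer(), pos = integer()))
  }
  # round-robin assignment of per-edge junction counts: every pass, each
  # interface takes one more junction as long as neither helix is saturated
  counts <- integer(m)
  part <- integer(n)
  repeat {
    progressed <- FALSE
    for (k in seq_len(m)) {
      a <- edges[k, 1L]; b <- edges[k, 2L]
      if (part[a] < target && part[b] < target) {
        counts[k] <- counts[k] + 1L
        part[a] <- part[a] + 1L
        part[b] <- part[b] + 1L
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  # on lattices whose adjacency cannot host a uniform per-helix density
  # (unbalanced bipartite grids), the saturating pass stops short; top up on
  # the least-loaded interfaces so the total junction count -- and with it
  # the average density -- is exact
  total_target <- as.integer(round(n * target / 2))
  while (sum(counts) < total_target) {
    load <- part[edges[, 1L]] + part[edges[, 2L]]
    k <- which.min(load)
    counts[k] <- counts[k] + 1L
    part[edges[k, 1L]] <- part[edges[k, 1L]] + 1L
    part[edges[k, 2L]] <- part[edges[k, 2L]] + 1L
  }

  colors <- greedy_edge_coloring(edges)
  nc <- max(colors)
  rows <- vector("list", m)
  for (k in seq_len(m)) {
    if (counts[k] == 0L) next
    sp <- bp / counts[k]
    offset <- ((colors[k] - 0.5) / nc - 0.5) * sp
    pos <- as.integer(round((seq_len(counts[k]) - 0.5) * sp + offset))
    pos <- pmin(pmax(pos, min_sep), bp - min_sep)
    rows[[k]] <- tibble(helix_a = edges[k, 1L], helix_b = edges[k, 2L], pos = pos)
  }
  jn <- dplyr::bind_rows(rows)
  repair_min_separation(jn, n, bp, min_sep)
}

# deterministically shift junctions right until all participations on the
# same helix are >= min_sep bp apart (no-op for the standard densities)
repair_min_separation <- function(jn, n, bp, min_sep, max_pass = 100L) {
  for (pass in seq_len(max_pass)) {
    moved <- FALSE
    for (h in seq_len(n)) {
      idx <- which(jn$helix_a == h | jn$helix_b == h)
      if (length(idx) < 2L) next
      idx <- idx[order(jn$pos[idx])]
      for (i in 2:length(idx)) {
        gap <- jn$pos[idx[i]] - jn$pos[idx[i - 1L]]
        if (gap < min_sep) {
          jn$pos[idx[i]] <- jn$pos[idx[i - 1L]] + min_sep
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  if (moved) {
    stop_validation("Could not separate junction blocks by %d bp; density too high.",
                    min_sep)
  }
  if (any(jn$pos >= bp)) {
    stop_validation("Junction density too high: repair pushed a junction past the helix end.")
  }
  jn
}

bundle_nicks <- function(jn, n, bp, n_nicks, min_sep) {
  if (n_nicks == 0L) return(tibble(helix = integer(), pos = integer()))
  hw <- (min_sep - 1L) %/% 2L  # half-width of a junction block
  rows <- vector("list", n)
  for (h in seq_len(n)) {
    ppos <- sort(c(jn$pos[jn$helix_a == h], jn$pos[jn$helix_b == h]))
    if (length(ppos) >= 2L) {
      lo <- ppos[-length(ppos)]
      hi <- ppos[-1L]
      # a gap can host a nick only if at least one element clears both
      # flanking junction blocks
      usable <- which(hi - lo >= 2L * hw + 2L)
      if (n_nicks > length(usable)) {
        stop_validation("Helix %d has %d usable junction gaps but %d nicks were requested.",
                        h, length(usable), n_nicks)
      }
      sel <- unique(as.integer(round(seq(1L, length(usable), length.out = n_nicks))))
      # rounding can merge neighbours; pad deterministically from unused gaps
      extra <- setdiff(seq_along(usable), sel)
      sel <- sort(c(sel, extra[seq_len(n_nicks - length(sel))]))
      g <- usable[sel]
      mids <- pmin(pmax(as.integer(floor((lo[g] + hi[g]) / 2)),
                        lo[g] + hw + 1L), hi[g] - hw - 1L)
    } else {
      mids <- pmin(pmax(as.integer(round((seq_len(n_nicks) - 0.5) * bp / n_nicks)),
                        1L), bp - 1L)
    }
    rows[[h]] <- tibble(helix = h, pos = mids)
  }
  dplyr::bind_rows(rows)
}

#' Built-in construct presets
#'
#' Named designs used throughout: the four two-helix nanobeams
#' (C85L/C85N/C170L/C170N: 3600 bp per helix, crossovers every 42 or 21 bp,
#' ligated or nicked) and the idealized multi-helix bundles 6HB (6 helices,
#' 428 nm) and 10HB (10 helices, 257 nm), both with 2 junction
#' participations and 0.5 nicks per helix per 21 bp on a honeycomb
#' cross-section.
#'
#' @param name One of `"C85L"`, `"C85N"`, `"C170L"`, `"C170N"`, `"6HB"`, `"10HB"`.
#' @return A [nanobeam_design()] object.
#' @export
#' @examples
#' design_summary(design_preset("C170L"))
design_preset <- function(name) {
  switch(as.character(name),
    C85L  = build_two_helix(3600, 42, ligated = TRUE,  name = "C85L"),
    C85N  = build_two_helix(3600, 42, ligated = FALSE, name = "C85N"),
    C170L = build_two_helix(3600, 21, ligated = TRUE,  name = "C170L"),
    C170N = build_two_helix(3600, 21, ligated = FALSE, name = "C170N"),
    `6HB`  = build_bundle(6, "honeycomb", 428, 2, 0.5, name = "6HB"),
    `10HB` = build_bundle(10, "honeycomb", 257, 2, 0.5, name = "10HB"),
    stop_validation("Unknown preset '%s'.", name)
  )
}

#' Summarize a design as a one-row tibble
#'
#' @param design A [nanobeam_design()] object.
#' @return Tibble with helix count, length, junction/nick counts and their
#'   per-helix densities per 21 bp.
#' @export
design_summary <- function(design) {
  stopifnot(inherits(design, "nanobeam_design"))
  n_j <- nrow(design$junctions)
  n_n <- nrow(design$nicks)
  bp <- design$bp_per_helix
  tibble(
    name = design$name,
    n_helices = design$n_helices,
    bp_per_helix = bp,
    length_nm = design$length_nm,
    packing = design$packing,
    n_junctions = n_j,
    n_nicks = n_n,
    junctions_per_helix_per_21bp = 2 * n_j / design$n_helices * 21 / bp,
    nicks_per_helix_per_21bp = n_n / design$n_helices * 21 / bp
  )
}

#' @export
print.nanobeam_design <- function(x, ...) {
  cat(sprintf("<nanobeam_design> %s\n", x$name))
  cat(sprintf("  %d helice(s) x %d bp (%.1f nm), %s packing\n",
              x$n_helices, x$bp_per_helix, x$length_nm, x$packing))
  cat(sprintf("  %d junctions, %d nicks\n", nrow(x$junctions), nrow(x$nicks)))
  invisible(x)
}

#' Read / write a design as JSON
#'
#' The on-disk schema is
#' `{name, n_helices, packing, bp_per_helix, rise_per_bp,
#'  junctions: [[helix_a, helix_b, pos], ...], nicks: [[helix, pos], ...]}`
#' with 1-based helix indices; the round trip through
#' `read_design(write_design(...))` reproduces the design exactly.
#'
#' @param design A [nanobeam_design()] object.
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()` the design.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "nanobeam_design"))
  obj <- list(
    name = design$name,
    n_helices = design$n_helices,
    packing = design$packing,
    bp_per_helix = design$bp_per_helix,
    rise_per_bp = design$rise_per_bp,
    junctions = unname(lapply(seq_len(nrow(design$junctions)), function(i) {
      as.integer(design$junctions[i, c("helix_a", "helix_b", "pos")])
    })),
    nicks = unname(lapply(seq_len(nrow(design$nicks)), function(i) {
      as.integer(design$nicks[i, c("helix", "pos")])
    }))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  junctions <- NULL
  if (length(obj$junctions) > 0) {
    jm <- matrix(as.integer(unlist(obj$junctions)), ncol = 3, byrow = !is.matrix(obj$junctions))
    if (is.matrix(obj$junctions)) jm <- matrix(as.integer(obj$junctions), ncol = 3)
    junctions <- tibble(helix_a = jm[, 1], helix_b = jm[, 2], pos = jm[, 3])
  }
  nicks <- NULL
  if (length(obj$nicks) > 0) {
    nm <- if (is.matrix(obj$nicks)) matrix(as.integer(obj$nicks), ncol = 2) else
      matrix(as.integer(unlist(obj$nicks)), ncol = 2, byrow = TRUE)
    nicks <- tibble(helix = nm[, 1], pos = nm[, 2])
  }
  nanobeam_design(obj$n_helices, obj$bp_per_helix, junctions, nicks,
                  packing = obj$packing, rise_per_bp = obj$rise_per_bp,
                  name = obj$name)
}
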