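#' Material and local-degradation parameters
#'
#' Element properties of the axial model. Every base pair is one axial spring
#' of stiffness `EA / rise_per_bp` (pN/nm). Elements inside a Holliday
#' junction block carry `alpha * EA / rise_per_bp`, elements at nicks
#' `beta * EA / rise_per_bp`. A junction degrades `n_hj` contiguous elements
#' per helix centred on the junction position; a nick degrades `n_nick`
#' elements centred on the nick element.
#'
#' @param EA Axial rigidity (stretch modulus) of intact B-form duplex, pN.
#' @param rise_per_bp Axial rise per base pair, nm.
#' @param alpha Holliday-junction degradation factor, in (0, 1].
#' @param beta Nick degradation factor, in (0, 1].
#' @param n_hj Base-pair span of the degraded block per helix per junction
#'   participation.
#' @param n_nick Base-pair span of the degraded block per nick.
#' @return An object of class `material_params`.
#' @export
#' @examples
#' material_params(alpha = 0.02, beta = 0.006)
material_params <- function(EA = 1100, rise_per_bp = 0.34, alpha = 1, beta = 1,
                            n_hj = 5L, n_nick = 1L) {
  out <- list(
    EA = check_scalar(EA, "EA", lower = 0, strict = TRUE),
    rise_per_bp = check_scalar(rise_per_bp, "rise_per_bp", lower = 0, strict = TRUE),
    alpha = check_scalar(alpha, "alpha", lower = 0, upper = 1, strict = TRUE),
    beta = check_scalar(beta, "beta", lower = 0, upper = 1, strict = TRUE),
    n_hj = check_scalar(n_hj, "n_hj", lower = 1, integer = TRUE),
    n_nick = check_scalar(n_nick, "n_nick", lower = 1, integer = TRUE)
  )
  structure(out, class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf(
    "<material_params> EA = %g pN, rise = %g nm/bp, alpha = %g, beta = %g, spans = %d/%d bp\n",
    x$EA, x$rise_per_bp, x$alpha, x$beta, x$n_hj, x$n_nick))
  invisible(x)
}

# label every element of every helix: 0 = intact duplex, 1 = HJ, 2 = NICK.
# Errors if degraded blocks overlap or fall outside the helix.
element_labels <- function(design, material) {
  bp <- design$bp_per_helix
  nh <- design$n_helices
  lab <- matrix(0L, nrow = bp, ncol = nh)

  block <- function(pos, span) (pos - (span - 1L) %/% 2L):(pos + span %/% 2L)

  jn <- design$junctions
  for (i in seq_len(nrow(jn))) {
    els <- block(jn$pos[i], material$n_hj)
    if (any(els < 1L | els > bp)) {
      stop_validation("Junction block at position %d extends outside helix (1..%d).",
                      jn$pos[i], bp)
    }
    for (h in c(jn$helix_a[i], jn$helix_b[i])) {
      if (any(lab[els, h] != 0L)) {
        stop_validation("Overlapping junction blocks on helix %d near position %d.",
                        h, jn$pos[i])
      }
      lab[els, h] <- 1L
    }
  }
  nk <- design$nicks
  for (i in seq_len(nrow(nk))) {
    els <- block(nk$pos[i], material$n_nick)
    if (any(els < 1L | els > bp)) {
      stop_validation("Nick block at position %d extends outside helix (1..%d).",
                      nk$pos[i], bp)
    }
    if (any(lab[els, nk$helix[i]] != 0L)) {
      stop_validation("Nick block on helix %d at position %d overlaps another degraded block.",
                      nk$helix[i], nk$pos[i])
    }
    lab[els, nk$helix[i]] <- 2L
  }
  lab
}

#' Assemble the axial spring network for a design
#'
#' Each base pair becomes one two-node axial spring; junction and nick blocks
#' carry degraded stiffness. Rigid ties constrain tied nodes to equal axial
#' displacement: one tie per junction at its centre, plus one tie per beam
#' end gathering all helices' terminal nodes into an end plate. One end plate
#' is fixed, the external force is applied to the other.
#'
#' @param design A [nanobeam_design()].
#' @param material A [material_params()].
#' @return An object of class `spring_system` holding per-element labels and
#'   stiffness values (pN/nm).
#' @export
assemble <- function(design, material = material_params()) {
  stopifnot(inherits(design, "nanobeam_design"))
  stopifnot(inherits(material, "material_params"))
  lab <- element_labels(design, material)
  k0 <- material$EA / material$rise_per_bp
  k_el <- matrix(k0 * c(1, material$alpha, material$beta)[lab + 1L],
                 nrow = nrow(lab), ncol = ncol(lab))
  structure(
    list(design = design, material = material, labels = lab, stiffness = k_el),
    class = "spring_system"
  )
}

#' @export
print.spring_system <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:2, labels = c("DS", "HJ", "NICK")))
  cat(sprintf("<spring_system> %s: %d nodes, %d springs (%s)\n",
              x$design$name,
              x$design$n_helices * (x$design$bp_per_helix + 1L),
              length(x$labels),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", ")))
  invisible(x)
}

# element label counts as a tibble (used in tests and summaries)
spring_counts <- function(system) {
  tab <- table(factor(system$labels, levels = 0:2, labels = c("DS", "HJ", "NICK")))
  tibble(label = names(tab), n_elements = as.integer(tab))
}

#' Solve the tension response of an assembled system
#'
#' Builds the reduced stiffness matrix with rigid ties handled by
#' degree-of-freedom merging (exactly rigid, no Lagrange multipliers), fixes
#' one end plate and applies `force` to the other, and returns the end-plate
#' displacement. The model is linear, so the extension is proportional to
#' the force.
#'
#' @param system A `spring_system` from [assemble()].
#' @param force Applied axial force, pN (>= 0).
#' @return Extension of the loaded end plate, nm.
#' @export
solve_tension <- function(system, force) {
  stopifnot(inherits(system, "spring_system"))
  force <- check_scalar(force, "force", lower = 0)
  force * compliance_nm_per_pN(system)
}

compliance_nm_per_pN <- function(system) {
  des <- system$design
  bp <- des$bp_per_helix
  nh <- des$n_helices
  npos <- bp + 1L

  node <- function(h, pos) (h - 1L) * npos + pos + 1L

  dof <- seq_len(nh * npos)
  dof[node(seq_len(nh), 0L)] <- node(1L, 0L)
  dof[node(seq_len(nh), bp)] <- node(1L, bp)
  jn <- des$junctions
  if (nrow(jn) > 0L) {
    dof[node(jn$helix_b, jn$pos)] <- node(jn$helix_a, jn$pos)
  }

  hidx <- rep(seq_len(nh), each = bp)
  eidx <- rep(seq_len(bp), times = nh)
  ia <- dof[node(hidx, eidx - 1L)]
  ib <- dof[node(hidx, eidx)]
  kv <- as.vector(system$stiffness)

  ids <- sort(unique(c(ia, ib)))
  ia <- match(ia, ids)
  ib <- match(ib, ids)
  nd <- length(ids)

  K <- sparseMatrix(
    i = c(ia, ib, ia, ib), j = c(ia, ib, ib, ia),
    x = c(kv, kv, -kv, -kv), dims = c(nd, nd)
  )

  fixed <- match(dof[node(1L, 0L)], ids)
  load <- match(dof[node(1L, bp)], ids)
  free <- setdiff(seq_len(nd), fixed)
  load_free <- match(load, free)
  f <- numeric(nd - 1L)
  f[load_free] <- 1

  u <- tryCatch(
    Matrix::solve(K[free, free, drop = FALSE], f),
    error = function(e) {
      stop_numeric("Spring system is singular (disconnected load path): %s",
                   conditionMessage(e))
    }
  )
  as.numeric(u[load_free])
}

#' Apparent axial stiffness of a design
#'
#' Solves the network at a reference force, takes the force-extension slope
#' (exact for this linear model) and multiplies it by the beam length:
#' `stiffness = slope * L0`, in pN.
#'
#' @param design A [nanobeam_design()].
#' @param material A [material_params()].
#' @param reference_force Force used for the slope evaluation, pN. Any
#'   positive value gives the same slope; recorded for provenance.
#' @return One-row tibble: `construct`, `L0_nm`, `slope_pN_per_nm`,
#'   `stiffness_pN`.
#' @export
#' @examples
#' apparent_stiffness(build_two_helix(210, 21), material_params(alpha = 0.02))
apparent_stiffness <- function(design, material = material_params(),
                               reference_force = 20) {
  check_scalar(reference_force, "reference_force", lower = 0, strict = TRUE)
  slope <- 1 / compliance_nm_per_pN(assemble(design, material))
  tibble(
    construct = design$name,
    L0_nm = design$length_nm,
    slope_pN_per_nm = slope,
    stiffness_pN = slope * design$length_nm
  )
}

# scalar shortcut used internally by the calibration loop
stiffness_scalar <- function(design, material) {
  design$length_nm / compliance_nm_per_pN(assemble(design, material))
}

#' Force-extension curve of a design
#'
#' @param design A [nanobeam_design()].
#' @param material A [material_params()].
#' @param forces Forces at which to evaluate the extension, pN.
#' @return Tibble with `force_pN` and `extension_nm`, passing through the
#'   origin and strictly increasing (linear model).
#' @export
force_extension <- function(design, material = material_params(),
                            forces = seq(5, 65, by = 5)) {
  if (any(forces < 0)) stop_validation("Forces must be non-negative.")
  compliance <- compliance_nm_per_pN(assemble(design, material))
  tibble(force_pN = as.numeric(forces), extension_nm = forces * compliance)
}

#' Closed-form homogenized stiffness for periodic designs
#'
#' Analytic oracle for beams whose junction/nick pattern repeats every 21 bp.
#' Per 21 bp repeat and per helix, `n_hj * j` elements carry stiffness
#' `alpha * k`, `n_nick * nu` elements carry `beta * k` and the rest are
#' intact, so the per-repeat series compliance in intact-element units is
#' `C = (21 - n_hj*j - n_nick*nu) + n_hj*j/alpha + n_nick*nu/beta` and the
#' bundle stiffness is `K = n_helices * EA * 21 / C`.
#'
#' @param n_helices Number of helices.
#' @param junctions_per_21bp Junction participations per helix per 21 bp (j).
#' @param nicks_per_21bp Nicks per helix per 21 bp (nu).
#' @param material A [material_params()].
#' @return Stiffness in pN (scalar).
#' @export
#' @examples
#' homogenized_stiffness(2, 1, 0, material_params(alpha = 0.0209))
homogenized_stiffness <- function(n_helices, junctions_per_21bp, nicks_per_21bp,
                                  material = material_params()) {
  n <- check_scalar(n_helices, "n_helices", lower = 1, integer = TRUE)
  j <- check_scalar(junctions_per_21bp, "junctions_per_21bp", lower = 0)
  nu <- check_scalar(nicks_per_21bp, "nicks_per_21bp", lower = 0)
  degraded <- material$n_hj * j + material$n_nick * nu
  if (degraded > 21) {
    stop_validation("Degraded span per repeat (%.2f bp) exceeds the 21 bp period.",
                    degraded)
  }
  c_rep <- (21 - degraded) + material$n_hj * j / material$alpha +
    material$n_nick * nu / material$beta
  n * material$EA * 21 / c_rep
}

#' Stiffness sweep over bundle size and packing
#'
#' Builds a bundle per helix count and packing, solves its tension response
#' and reports the apparent stiffness and its value normalized to the
#' stretch modulus of a single intact duplex (`K / EA`).
#'
#' @param n_helices Integer vector of helix counts.
#' @param packing Character vector of packings to sweep.
#' @param material A [material_params()] (typically carrying calibrated
#'   `alpha`, `beta`).
#' @param length_nm Beam length, nm.
#' @param junctions_per_21bp,nicks_per_21bp Per-helix densities handed to
#'   [build_bundle()].
#' @return Tibble: `n_helices`, `packing`, `stiffness_pN`,
#'   `normalized_stiffness`.
#' @export
bundle_sweep <- function(n_helices = c(2, 6, 9, 10, 16),
                         packing = c("honeycomb", "square"),
                         material = material_params(),
                         length_nm = 1224,
                         junctions_per_21bp = 1, nicks_per_21bp = 0.5) {
  grid <- tidyr::expand_grid(packing = packing, n_helices = as.integer(n_helices))
  purrr::pmap_dfr(grid, function(packing, n_helices) {
    des <- build_bundle(n_helices, packing, length_nm,
                        junctions_per_21bp, nicks_per_21bp,
                        rise_per_bp = material$rise_per_bp)
    k <- stiffness_scalar(des, material)
    tibble(n_helices = n_helices, packing = packing,
           stiffness_pN = k, normalized_stiffness = k / material$EA)
  })
}
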