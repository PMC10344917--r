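#' Van der Waals radius lookup
#'
#' Bondi-style van der Waals radii in Angstrom, read from the versioned
#' table shipped at \code{inst/extdata/vdw_radii.csv}. Unknown elements are
#' a lookup error naming the element.
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  tab <- vdw_table()
  el <- toupper(element)
  r <- tab$radius[match(el, toupper(tab$element))]
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  r
}

vdw_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "vdw_radii.csv", package = "ternarySAR")
      cache <<- utils::read.csv(path, stringsAsFactors = FALSE)
    }
    cache
  }
})

#' Labelled atom-set model of a ternary complex
#'
#' A light container for candidate ternary-complex coordinates: each atom
#' carries an element, Cartesian coordinates (Angstrom), a van der Waals
#' radius (looked up from the packaged table when not supplied), a
#' heavy-atom flag, a component label (\code{ligase}, \code{target} or
#' \code{protac}) and an optional sub-label within the PROTAC
#' (\code{ligase_ligand}, \code{linker}, \code{target_warhead}).
#'
#' @param element Element symbols.
#' @param x,y,z Coordinates (Angstrom), finite.
#' @param component Component label per atom.
#' @param subcomponent Optional sub-label per atom (PROTAC moieties).
#' @param radius Optional radii; defaults to [vdw_radius()] lookup.
#' @return Object of class \code{structure_model}: list with an
#'   \code{atoms} data.frame.
#' @export
structure_model <- function(element, x, y, z, component,
                            subcomponent = NA_character_, radius = NULL) {
  n <- length(element)
  stopifnot(length(x) == n, length(y) == n, length(z) == n)
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z)))
    stop("coordinates must be finite")
  component <- rep_len(as.character(component), n)
  bad <- setdiff(unique(component), c("ligase", "target", "protac"))
  if (length(bad))
    stop("unknown component label(s): ", paste(bad, collapse = ", "))
  subcomponent <- rep_len(as.character(subcomponent), n)
  if (is.null(radius)) radius <- vdw_radius(element)
  structure(list(atoms = data.frame(
    element = element, x = x, y = y, z = z, radius = radius,
    heavy = toupper(element) != "H",
    component = component, subcomponent = subcomponent,
    stringsAsFactors = FALSE)), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms (%d heavy)\n",
              nrow(x$atoms), sum(x$atoms$heavy)))
  print(table(x$atoms$component))
  invisible(x)
}

model_xyz <- function(model, component = NULL, heavy_only = TRUE,
                      subcomponent = NULL) {
  a <- model$atoms
  sel <- rep(TRUE, nrow(a))
  if (!is.null(component)) sel <- sel & a$component %in% component
  if (!is.null(subcomponent)) sel <- sel & a$subcomponent %in% subcomponent
  if (heavy_only) sel <- sel & a$heavy
  as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
}

#' Count steric clashes between two atom sets
#'
#' Number of cross-set heavy-atom pairs closer than \code{cutoff}
#' (Euclidean distance, default 2.2 Angstrom), the criterion used to
#' discard assembled ternary-complex models with interpenetrating
#' components. An empty subset counts zero clashes with a warning.
#'
#' @param model A [structure_model()].
#' @param comp_a,comp_b Disjoint component selections: component labels,
#'   or for the PROTAC side the label \code{"protac"}.
#' @param cutoff Distance cutoff (Angstrom).
#' @return Integer clash count.
#' @export
count_clashes <- function(model, comp_a, comp_b, cutoff = 2.2) {
  stopifnot(inherits(model, "structure_model"))
  if (length(intersect(comp_a, comp_b)))
    stop("component selections must be disjoint")
  a <- model_xyz(model, comp_a)
  b <- model_xyz(model, comp_b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    warning("empty atom subset: clash count is 0")
    return(0L)
  }
  clash_count_xyz(a, b, cutoff)
}

# cross-pair count with distance < cutoff; vectorised row-block scan
clash_count_xyz <- function(a, b, cutoff) {
  c2 <- cutoff^2
  total <- 0L
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1L] - a[i, 1L])^2 + (b[, 2L] - a[i, 2L])^2 +
      (b[, 3L] - a[i, 3L])^2
    total <- total + sum(d2 < c2)
  }
  as.integer(total)
}

#' Clash-based assembly filter for candidate models
#'
#' Keeps an assembled ternary-complex model when its protein-protein clash
#' count is at most \code{max_pp} (default 5) and its protein-PROTAC clash
#' count at most \code{max_pl} (default 2). Vectorised over models.
#'
#' @param clashes_pp,clashes_pl Non-negative clash counts.
#' @param max_pp,max_pl Thresholds (inclusive).
#' @return data.frame with \code{keep} and a human-readable \code{reason}.
#' @export
assembly_filter <- function(clashes_pp, clashes_pl, max_pp = 5L, max_pl = 2L) {
  if (any(clashes_pp < 0) || any(clashes_pl < 0)) stop("counts must be >= 0")
  keep <- clashes_pp <= max_pp & clashes_pl <= max_pl
  reason <- ifelse(keep, "pass",
    ifelse(clashes_pp > max_pp & clashes_pl > max_pl,
           "protein-protein and protein-PROTAC clashes exceed cutoffs",
           ifelse(clashes_pp > max_pp,
                  sprintf("protein-protein clashes %d > %d", clashes_pp, max_pp),
                  sprintf("protein-PROTAC clashes %d > %d", clashes_pl, max_pl))))
  data.frame(keep = keep, reason = reason, stringsAsFactors = FALSE)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Proper rotation and translation minimising the RMSD between two equal
#' length coordinate sets, with the determinant sign corrected so only
#' rotations (no reflections) are returned.
#'
#' @param a,b n x 3 coordinate matrices (Angstrom), n >= 3 non-collinear
#'   rows; \code{b} is superposed onto \code{a}.
#' @return List with \code{rotation} (3 x 3), \code{translation} (length
#'   3), \code{rmsd}, and \code{transform(m)} applying the fit to any
#'   coordinate matrix.
#' @export
kabsch <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3L)
    stop("`a` and `b` must be equal-size n x 3 matrices")
  if (nrow(a) < 3L) stop("need >= 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2L, ca); b0 <- sweep(b, 2L, cb)
  s <- svd(crossprod(b0, a0))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  b_fit <- b0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((a0 - b_fit)^2)))
  trans <- ca - as.numeric(rot %*% cb)
  list(rotation = rot, translation = trans, rmsd = rmsd,
       transform = function(m) sweep(as.matrix(m) %*% t(rot), 2L, trans, `+`))
}

#' Minimal RMSD after optimal rigid superposition
#'
#' @inheritParams kabsch
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b) kabsch(a, b)$rmsd

#' Warhead-placement similarity between two ternary-complex models
#'
#' Compares where two candidate models place the target warhead after both
#' are expressed in the ligase frame: model \code{b}'s ligase heavy atoms
#' are superposed onto model \code{a}'s (Kabsch), then the warhead heavy
#' atoms are summarised by their centre of geometry (COG) and the
#' principal axes of their coordinate scatter. Models are similar when the
#' COG distance is below \code{cog_cutoff} (6 Angstrom) and the deviations
#' of both the first and second principal axes are below
#' \code{angle_cutoff} (20 degrees); axis angles are folded to
#' \[0, 90\] degrees because a principal axis has no sign.
#'
#' @param model_a,model_b [structure_model()] objects of the same system;
#'   warhead atoms are those with \code{subcomponent ==
#'   "target_warhead"}, >= 3 per model.
#' @param cog_cutoff COG distance threshold (Angstrom).
#' @param angle_cutoff Per-axis angular threshold (degrees).
#' @param align Superpose on the shared ligase first (default TRUE;
#'   requires equal ligase heavy-atom counts).
#' @return List with \code{cog_distance}, \code{axis_angle_1},
#'   \code{axis_angle_2} and logical \code{similar}.
#' @export
warhead_similarity <- function(model_a, model_b, cog_cutoff = 6,
                               angle_cutoff = 20, align = TRUE) {
  wa <- model_xyz(model_a, subcomponent = "target_warhead")
  wb <- model_xyz(model_b, subcomponent = "target_warhead")
  if (nrow(wa) < 3L || nrow(wb) < 3L)
    stop("principal axes undefined: need >= 3 warhead heavy atoms")
  if (align) {
    la <- model_xyz(model_a, "ligase")
    lb <- model_xyz(model_b, "ligase")
    if (nrow(la) >= 3L && nrow(la) == nrow(lb)) {
      fit <- kabsch(la, lb)
      wb <- fit$transform(wb)
    }
  }
  cog_a <- colMeans(wa); cog_b <- colMeans(wb)
  dist <- sqrt(sum((cog_a - cog_b)^2))
  axes <- function(m) eigen(stats::cov(m), symmetric = TRUE)$vectors
  ea <- axes(wa); eb <- axes(wb)
  ang <- function(u, v) {
    c0 <- min(1, abs(sum(u * v) / sqrt(sum(u^2) * sum(v^2))))
    acos(c0) * 180 / pi
  }
  a1 <- ang(ea[, 1L], eb[, 1L])
  a2 <- ang(ea[, 2L], eb[, 2L])
  list(cog_distance = dist, axis_angle_1 = a1, axis_angle_2 = a2,
       similar = dist < cog_cutoff && a1 < angle_cutoff && a2 < angle_cutoff)
}

#' Strain/RMSD model pruning and final selection
#'
#' Two-stage verdict on a relaxed candidate model from externally supplied
#' linker strain energy (kcal/mol; computed by a force-field engine outside
#' this package) and the target-warhead heavy-atom RMSD (Angstrom) against
#' the reference placement. Pruning retains models with strain at most
#' \code{prune_cutoff} (4 kcal/mol); final selection requires strain within
#' thermal fluctuation (\code{select_strain}, 0.6 kcal/mol) and warhead
#' RMSD below \code{select_rmsd} (3 Angstrom). A missing strain value fails
#' pruning with reason \code{"no strain available"}. Vectorised.
#'
#' @param strain Linker strain energies (kcal/mol); \code{NA} allowed.
#' @param warhead_rmsd Warhead heavy-atom RMSD (Angstrom).
#' @param prune_cutoff,select_strain,select_rmsd Thresholds.
#' @return data.frame with \code{prune_pass}, \code{select_pass},
#'   \code{reason}.
#' @export
model_selection <- function(strain, warhead_rmsd, prune_cutoff = 4,
                            select_strain = 0.6, select_rmsd = 3) {
  n <- max(length(strain), length(warhead_rmsd))
  strain <- rep_len(strain, n); warhead_rmsd <- rep_len(warhead_rmsd, n)
  prune <- !is.na(strain) & strain <= prune_cutoff
  select <- prune & !is.na(warhead_rmsd) &
    strain <= select_strain & warhead_rmsd < select_rmsd
  reason <- ifelse(is.na(strain), "no strain available",
    ifelse(!prune, sprintf("strain %.2f > %.2f kcal/mol", strain, prune_cutoff),
      ifelse(select, "selected",
        ifelse(strain > select_strain,
               sprintf("strain %.2f above thermal fluctuation %.2f",
                       strain, select_strain),
               sprintf("warhead RMSD %.2f >= %.2f A", warhead_rmsd,
                       select_rmsd)))))
  data.frame(prune_pass = prune, select_pass = select, reason = reason,
             stringsAsFactors = FALSE)
}

# deterministic quasi-uniform unit-sphere point set (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom and total SASA of the heavy atoms of a model: each atom's
#' sphere of radius \code{r + probe} is sampled with a deterministic
#' Fibonacci lattice of \code{n_points} quasi-uniform points, and the
#' accessible fraction (points outside every neighbour's expanded sphere)
#' scales the analytic sphere area \code{4 pi (r + probe)^2}. The lattice
#' is deterministic, so values are reproducible bit-for-bit. Hydrogens are
#' ignored.
#'
#' @param model A [structure_model()] (or an atoms-like data.frame with
#'   \code{x, y, z, radius} columns, all taken as heavy).
#' @param probe Probe radius (Angstrom), default 1.4 (water).
#' @param n_points Lattice points per atom, default 960
#'   (quadrature error well under 0.5 percent for overlapping spheres).
#' @return List with \code{total} (Angstrom^2) and \code{per_atom}.
#' @examples
#' m <- structure_model("C", 0, 0, 0, "protac", radius = 1.6)
#' sasa(m)$total  # ~ 4 * pi * 3^2
#' @export
sasa <- function(model, probe = 1.4, n_points = 960L) {
  a <- if (inherits(model, "structure_model")) {
    model$atoms[model$atoms$heavy, , drop = FALSE]
  } else as.data.frame(model)
  n <- nrow(a)
  if (n == 0L) return(list(total = 0, per_atom = numeric(0)))
  if (any(!is.finite(a$radius)) || any(a$radius <= 0))
    stop("all heavy atoms need a positive radius")
  pts <- fibonacci_sphere(n_points)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rext <- a$radius + probe
  per <- numeric(n)
  for (i in seq_len(n)) {
    ri <- rext[i]
    # neighbours whose expanded spheres can reach atom i's surface
    dc <- sqrt(rowSums(sweep(xyz, 2L, xyz[i, ])^2))
    nb <- which(dc < ri + rext & seq_len(n) != i)
    if (!length(nb)) { per[i] <- 4 * pi * ri^2; next }
    sp <- sweep(pts * ri, 2L, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- (sp[, 1L] - xyz[j, 1L])^2 + (sp[, 2L] - xyz[j, 2L])^2 +
        (sp[, 3L] - xyz[j, 3L])^2
      free <- free & d2 >= rext[j]^2
      if (!any(free)) break
    }
    per[i] <- 4 * pi * ri^2 * sum(free) / n_points
  }
  list(total = sum(per), per_atom = per)
}

#' Buried surface area of a labelled ternary complex
#'
#' Interface area buried on ternary-complex formation, from component-wise
#' SASA: \code{bsa_total = SASA(ligase) + SASA(target) + SASA(protac) -
#' SASA(complex)}. The protein-protein term is computed the same way on
#' the two-protein sub-system with the PROTAC removed, and the
#' protein-PROTAC term is the remainder, so the two terms sum to the total
#' by construction. Small negative quadrature residues are clamped to 0.
#'
#' @param model A [structure_model()] with all three components labelled.
#' @param probe,n_points As in [sasa()].
#' @return List with \code{bsa_total}, \code{bsa_protein_protein},
#'   \code{bsa_protein_protac} (Angstrom^2).
#' @export
buried_surface_area <- function(model, probe = 1.4, n_points = 960L) {
  stopifnot(inherits(model, "structure_model"))
  comps <- c("ligase", "target", "protac")
  have <- unique(model$atoms$component)
  if (!all(comps %in% have))
    stop("missing component label(s): ",
         paste(setdiff(comps, have), collapse = ", "))
  sub <- function(keep) {
    m <- model
    m$atoms <- m$atoms[m$atoms$component %in% keep, , drop = FALSE]
    m
  }
  s_l <- sasa(sub("ligase"), probe, n_points)$total
  s_t <- sasa(sub("target"), probe, n_points)$total
  s_p <- sasa(sub("protac"), probe, n_points)$total
  s_all <- sasa(model, probe, n_points)$total
  s_lt <- sasa(sub(c("ligase", "target")), probe, n_points)$total
  bsa_total <- max(0, s_l + s_t + s_p - s_all)
  bsa_pp <- max(0, s_l + s_t - s_lt)
  bsa_pl <- max(0, bsa_total - bsa_pp)
  list(bsa_total = bsa_total, bsa_protein_protein = bsa_pp,
       bsa_protein_protac = bsa_pl)
}

#' Read a ternary-complex model from a PDB file
#'
#' Loads coordinates with \pkg{bio3d} (first model, altloc "A" preferred)
#' and maps chains and residue names to components: chains listed under
#' \code{components$ligase} and \code{components$target} become the two
#' proteins, and HETATM residues named in \code{components$protac} become
#' the PROTAC. An optional \code{components$warhead} (vector of atom
#' serial numbers) tags the target-warhead atoms.
#'
#' @param file Path to a PDB file.
#' @param components List with \code{ligase}, \code{target} (chain IDs),
#'   \code{protac} (residue names), optional \code{warhead} (atom
#'   serials).
#' @return A [structure_model()].
#' @export
read_ternary_pdb <- function(file, components) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the `bio3d` package")
  stopifnot(all(c("ligase", "target", "protac") %in% names(components)))
  pdb <- bio3d::read.pdb(file, multi = FALSE)
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  comp <- rep(NA_character_, nrow(at))
  comp[at$chain %in% components$ligase] <- "ligase"
  comp[at$chain %in% components$target] <- "target"
  comp[at$resid %in% components$protac] <- "protac"
  keep <- !is.na(comp)
  if (!any(keep)) stop("component map matched no atoms")
  at <- at[keep, , drop = FALSE]; comp <- comp[keep]
  sub <- rep(NA_character_, nrow(at))
  if (!is.null(components$warhead))
    sub[at$eleno %in% components$warhead & comp == "protac"] <- "target_warhead"
  el <- at$elesy
  if (is.null(el) || all(is.na(el) | el == ""))
    el <- substr(trimws(at$elety), 1L, 1L)
  structure_model(element = trimws(el), x = at$x, y = at$y, z = at$z,
                  component = comp, subcomponent = sub)
}
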