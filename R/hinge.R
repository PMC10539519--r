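#' Domain partitions for hinge-motion analysis
#'
#' Partitions the residues of a hinge-bending protein into a large fixed
#' domain, a smaller moving domain and (optionally) the hinge-bending
#' residues connecting them. Automatic domain decomposition (as done by
#' DynDom-style tools) is not performed here; partitions are supplied by
#' the user or read from a config file.
#'
#' @param fixed,moving integer vectors of author residue numbers.
#' @param hinge integer vector of hinge-bending residue numbers
#'   (may be empty).
#' @param chain chain identifier the partition refers to (`"*"` = all).
#' @return An object of class `DomainPartition`.
#' @export
domain_partition <- function(fixed, moving, hinge = integer(0), chain = "*") {
  fixed <- as.integer(fixed); moving <- as.integer(moving)
  hinge <- as.integer(hinge)
  if (length(fixed) < 3 || length(moving) < 3)
    stop("fixed and moving domains each need at least 3 residues")
  if (length(intersect(fixed, moving)) || length(intersect(fixed, hinge)) ||
      length(intersect(moving, hinge)))
    stop("fixed, moving and hinge residue sets must be disjoint")
  structure(list(fixed = fixed, moving = moving, hinge = hinge,
                 chain = chain), class = "DomainPartition")
}

#' Read a domain partition from a YAML config block
#'
#' Expected keys: `fixed`, `moving`, optional `hinge`, `chain`; each
#' residue set is a list of `from-to` range strings or integers.
#' @param path YAML file path.
#' @return A [domain_partition()].
#' @export
read_partition <- function(path) {
  y <- yaml::read_yaml(path)
  expand <- function(v) {
    if (is.null(v)) return(integer(0))
    unlist(lapply(v, function(r) {
      if (is.character(r) && grepl("-", r)) {
        ft <- as.integer(strsplit(r, "-", fixed = TRUE)[[1]])
        seq(ft[1], ft[2])
      } else as.integer(r)
    }))
  }
  domain_partition(expand(y$fixed), expand(y$moving), expand(y$hinge),
                   chain = if (is.null(y$chain)) "*" else y$chain)
}

sel_for <- function(part, resnos, class = "CA") {
  atom_selection(chain = part$chain,
                 resno_ranges = cbind(resnos, resnos), atom_class = class)
}

#' Hinge rotation between two conformations
#'
#' Superposes the fixed domains (CA atoms) of the two structures, then
#' decomposes the residual rigid transform of the moving domain into
#' screw form: rotation angle (from the rotation-matrix trace), screw
#' axis (direction + a point on the axis) and the translation component
#' parallel to the axis. Also reports per-residue CA displacements in
#' the fixed-domain frame.
#'
#' @param open_s,closed_s Structures sharing topology over the partition.
#' @param part [domain_partition()].
#' @param angle_floor degrees; below this the motion is reported as null
#'   (angle 0, no axis). Default 1e-4.
#' @return An object of class `HingeMotion`: list with `rotation_angle`
#'   (degrees), `axis` (unit 3-vector or NULL), `axis_point` (a point on
#'   the screw axis, Angstrom, or NULL), `axis_translation` (Angstrom),
#'   `null_axis` flag, and `per_residue_ca_displacement` (data.frame).
#' @export
domain_rotation <- function(open_s, closed_s, part, angle_floor = 1e-4) {
  fit <- superpose(closed_s, open_s, sel_for(part, part$fixed, "CA"))
  closed_al <- closed_s
  coords(closed_al) <- apply_transform(fit$transform, coords(closed_s))

  msel <- sel_for(part, part$moving, "CA")
  m <- match_atoms(open_s, closed_al, msel)
  if (length(m$a) < 3) stop("moving domain has fewer than 3 CA atoms")
  X <- coords(open_s, m$a)
  Y <- coords(closed_al, m$b)
  kb <- tryCatch(kabsch(X, Y), error = function(e)
    stop("degenerate moving-domain geometry: ", conditionMessage(e)))
  R <- kb$transform$rotation
  tvec <- kb$transform$translation

  tr <- sum(diag(R))
  angle <- acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi

  disp <- per_residue_displacement(open_s, closed_al, part)

  if (angle < angle_floor) {
    return(structure(list(rotation_angle = 0, axis = NULL, axis_point = NULL,
                          axis_translation = 0, null_axis = TRUE,
                          per_residue_ca_displacement = disp),
                     class = "HingeMotion"))
  }

  sin_th <- sin(angle * pi / 180)
  if (abs(sin_th) > 1e-6) {
    u <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin_th)
  } else {
    # angle near 180: axis from the eigenvector of R with eigenvalue +1
    ev <- eigen(R)
    i <- which.min(abs(ev$values - 1))
    u <- Re(ev$vectors[, i])
  }
  u <- u / sqrt(sum(u^2))

  t_par <- sum(tvec * u)
  t_perp <- tvec - t_par * u
  # point on the axis: (I - R) p = t_perp, solved in the plane normal to u
  A <- diag(3) - R
  sv <- svd(A)
  dinv <- ifelse(sv$d > 1e-9, 1 / sv$d, 0)
  p <- as.numeric(sv$v %*% (dinv * crossprod(sv$u, t_perp)))

  structure(list(rotation_angle = angle, axis = u, axis_point = p,
                 axis_translation = t_par, null_axis = FALSE,
                 per_residue_ca_displacement = disp),
            class = "HingeMotion")
}

#' @export
print.HingeMotion <- function(x, ...) {
  if (x$null_axis) {
    cat("HingeMotion: no detectable rotation (null axis)\n")
  } else {
    cat(sprintf("HingeMotion: %.3f degree rotation about axis (%.3f, %.3f, %.3f)\n",
                x$rotation_angle, x$axis[1], x$axis[2], x$axis[3]))
    cat(sprintf("  axis-parallel translation: %.3f A\n", x$axis_translation))
  }
  invisible(x)
}

per_residue_displacement <- function(a, b_aligned, part) {
  resnos <- sort(c(part$fixed, part$moving, part$hinge))
  sel <- sel_for(part, resnos, "CA")
  m <- match_atoms(a, b_aligned, sel)
  X <- coords(a, m$a); Y <- coords(b_aligned, m$b)
  data.frame(chain = a$atoms$chain[m$a], resno = a$atoms$resno[m$a],
             displacement = sqrt(rowSums((X - Y)^2)))
}

#' CA displacement statistics for a residue range
#'
#' Superposes `b` onto `a` using `fit_sel` (typically the fixed-domain
#' CA atoms), then reports the pairwise CA distance for each residue in
#' `target_range` plus their mean and sample standard deviation.
#'
#' @param a,b Structures.
#' @param target_range integer vector of residue numbers (e.g.
#'   `355:365` for the active-site helix).
#' @param fit_sel [atom_selection()] used for superposition.
#' @param chain chain of the target residues (`"*"` = all).
#' @return list with `mean`, `sd` (Angstrom) and `per_residue`
#'   data.frame.
#' @export
ca_displacement_stats <- function(a, b, target_range, fit_sel,
                                  chain = "*") {
  fit <- superpose(b, a, fit_sel)
  b_al <- b
  coords(b_al) <- apply_transform(fit$transform, coords(b))
  sel <- atom_selection(chain = chain,
                        resno_ranges = cbind(target_range, target_range),
                        atom_class = "CA")
  ia <- select_atoms(a, sel)
  found <- a$atoms$resno[ia]
  missing <- setdiff(target_range, found)
  if (length(missing) > 0)
    stop("missing CA for residue(s): ", paste(missing, collapse = ", "))
  m <- match_atoms(a, b_al, sel)
  X <- coords(a, m$a); Y <- coords(b_al, m$b)
  d <- sqrt(rowSums((X - Y)^2))
  list(mean = mean(d), sd = if (length(d) > 1) sd(d) else 0,
       per_residue = data.frame(chain = a$atoms$chain[m$a],
                                resno = a$atoms$resno[m$a],
                                displacement = d))
}
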