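# tunnel_profiler: central-axis estimation, HOLE-style maximal-ball radius
# profile, rod length, tunnel continuity and point-mutation blockage.

#' Estimate the central axis of an elongated model
#'
#' Sliding-window CA centroids in sequence order trace the centerline even
#' when the rod curves (a straight PCA axis would not). The centroid
#' polyline is smoothed with a centered moving average and resampled at
#' uniform arclength. Sequence-order centroids cancel helical/solenoid
#' winding because each window averages whole turns.
#'
#' @param model [structure_model()]
#' @param window residues per centroid window (default 50)
#' @param step arclength resampling step, Angstrom (default 2)
#' @param smooth moving-average width (odd, default 5) applied to the
#'   centroid polyline before resampling
#' @return `axis_polyline`: data.frame with arclength `s` and `x`,`y`,`z`.
#'   Attribute `flagged` is TRUE (with a warning) when the centerline is
#'   degenerate — the raw centroid polyline turns erratically (mean cosine
#'   of consecutive turning angles below 0.5) or its arclength collapses to
#'   under half the model's principal-axis extent; both are signatures of
#'   atoms that are not in spatial sequence order.
#' @export
estimate_axis <- function(model, window = 50, step = 2, smooth = 5) {
  CA <- ca_coords(model)
  n <- nrow(CA)
  if (n < 2 * window) {
    stop("too few CA residues (", n, ") for axis estimation with window ", window)
  }
  m <- n - window + 1
  # running window means via cumulative sums
  cs <- apply(rbind(0, CA), 2, cumsum)
  cen <- (cs[(window + 1):(n + 1), , drop = FALSE] - cs[1:m, , drop = FALSE]) / window
  # smoothness of the raw centerline: consecutive steps of a genuine rod are
  # nearly parallel; spatially shuffled atoms give a random-walk polyline
  step_vec <- diff(cen)
  step_len <- sqrt(rowSums(step_vec^2))
  nz <- which(step_len[-length(step_len)] > 1e-12 & step_len[-1] > 1e-12)
  mean_turn_cos <- if (length(nz) > 0) {
    mean(rowSums(step_vec[nz, , drop = FALSE] * step_vec[nz + 1, , drop = FALSE]) /
           (step_len[nz] * step_len[nz + 1]))
  } else 1
  if (smooth > 1) {
    half <- floor(smooth / 2)
    sm <- cen
    for (k in seq_len(m)) {
      lo <- max(1, k - half); hi <- min(m, k + half)
      sm[k, ] <- colMeans(cen[lo:hi, , drop = FALSE])
    }
    cen <- sm
  }
  seg <- sqrt(rowSums(diff(cen)^2))
  s_raw <- c(0, cumsum(seg))
  total <- s_raw[length(s_raw)]
  flagged <- FALSE
  ext <- rod_length(model)$angstrom
  if (mean_turn_cos < 0.5 || total < 0.5 * ext) {
    warning("axis centerline is degenerate (mean turning cosine ",
            round(mean_turn_cos, 2), ", arclength ", round(total, 1),
            " A vs extent ", round(ext, 1),
            " A); atoms may not be in spatial sequence order")
    flagged <- TRUE
  }
  s_new <- seq(0, total, by = step)
  if (s_new[length(s_new)] < total) s_new <- c(s_new, total)
  ax <- data.frame(
    s = s_new,
    x = approx(s_raw, cen[, 1], xout = s_new, ties = "ordered")$y,
    y = approx(s_raw, cen[, 2], xout = s_new, ties = "ordered")$y,
    z = approx(s_raw, cen[, 3], xout = s_new, ties = "ordered")$y
  )
  structure(ax, class = c("axis_polyline", "data.frame"),
            step = step, flagged = flagged)
}

#' Maximal-ball radius profile along an axis
#'
#' HOLE-style with fixed centers: at each axis station the radius is the
#' largest sphere centered there that touches no atom's van der Waals
#' surface, `min over atoms (|station - atom| - vdW)`. Negative values
#' (axis inside an atom) are clamped to 0 and flagged. Lining residues are
#' those owning an atom whose center lies within `radius + shell` of the
#' station; their mean Kyte-Doolittle hydropathy summarizes the chemical
#' character of the tunnel wall. Keeping centers on the axis (no ball
#' wiggling) makes the profile deterministic and a conservative lower bound
#' on the true pore radius.
#'
#' @param model [structure_model()]
#' @param axis [estimate_axis()] output (or any data.frame with `s,x,y,z`)
#' @param shell lining shell thickness beyond the ball radius, Angstrom
#'   (default 3)
#' @return `axis_profile`: data.frame with `s`, station `x,y,z`, `radius`,
#'   `n_lining`, `mean_hydropathy`, `clamped`; attribute `lining` is a list
#'   of lining residue numbers per station
#' @export
radius_profile <- function(model, axis, shell = 3) {
  a <- model$atoms
  if (nrow(a) == 0) stop("empty model")
  X <- atom_coords(model)
  vdw <- a$vdw_radius
  kd <- kd_scale()
  res_letters <- aa_three_to_one(a$residue_name)
  n_st <- nrow(axis)
  radius <- numeric(n_st); nl <- integer(n_st); mh <- rep(NA_real_, n_st)
  clamped <- logical(n_st)
  lining <- vector("list", n_st)
  P <- as.matrix(axis[, c("x", "y", "z")])
  for (k in seq_len(n_st)) {
    d <- sqrt(rowSums(sweep(X, 2, P[k, ])^2))
    r <- min(d - vdw)
    if (r < 0) { r <- 0; clamped[k] <- TRUE }
    radius[k] <- r
    lin <- d <= r + shell
    resl <- unique(a$residue_number[lin])
    lining[[k]] <- resl
    nl[k] <- length(resl)
    if (length(resl) > 0) {
      letters1 <- res_letters[match(resl, a$residue_number)]
      h <- kd[letters1]
      mh[k] <- mean(h, na.rm = TRUE)
    }
  }
  if (any(clamped)) {
    warning(sum(clamped), " station(s) had the axis inside an atom; radius clamped to 0")
  }
  structure(
    data.frame(s = axis$s, x = P[, 1], y = P[, 2], z = P[, 3],
               radius = radius, n_lining = nl, mean_hydropathy = mh,
               clamped = clamped),
    class = c("axis_profile", "data.frame"),
    shell = shell, lining = lining
  )
}

#' Rod length of a model
#'
#' Extent of the CA coordinates along the first principal axis (max minus
#' min projection): an end-to-end measure, deliberately straight-line even
#' for a curved rod. The curved centerline length is available as the total
#' arclength of [estimate_axis()].
#'
#' @param model [structure_model()]
#' @return list with `angstrom` and `nm`
#' @export
rod_length <- function(model) {
  CA <- ca_coords(model)
  if (nrow(CA) < 2) stop("need at least 2 CA atoms")
  Xc <- sweep(CA, 2, colMeans(CA))
  v1 <- svd(Xc, nu = 0, nv = 1)$v[, 1]
  proj <- Xc %*% v1
  len <- max(proj) - min(proj)
  list(angstrom = as.numeric(len), nm = as.numeric(len) / 10)
}

#' Summarize tunnel continuity and character
#'
#' A tunnel counts as continuous when the profile radius admits the probe
#' at every interior station; the first and last `mouth_frac` of the
#' arclength are excluded because terminal stations have no enclosing wall.
#' The package's operational definition of a "hydrophobic tunnel" is:
#' continuous at the probe radius AND mean lining hydropathy > 0.
#'
#' @param profile [radius_profile()] output
#' @param probe probe radius, Angstrom (default 1.4, a water molecule)
#' @param mouth_frac fraction of arclength excluded at each end (default 0.05)
#' @return list with `continuous`, `min_radius`, `argmin_s`,
#'   `mean_lining_hydropathy`, `hydrophobic`, `n_interior_stations`
#' @export
tunnel_summary <- function(profile, probe = 1.4, mouth_frac = 0.05) {
  if (nrow(profile) == 0) stop("empty profile")
  smax <- max(profile$s)
  interior <- profile$s >= mouth_frac * smax & profile$s <= (1 - mouth_frac) * smax
  if (!any(interior)) interior <- rep(TRUE, nrow(profile))
  p <- profile[interior, , drop = FALSE]
  k <- which.min(p$radius)
  mh <- mean(p$mean_hydropathy, na.rm = TRUE)
  continuous <- all(p$radius >= probe)
  list(
    continuous = continuous,
    min_radius = p$radius[k],
    argmin_s = p$s[k],
    mean_lining_hydropathy = mh,
    hydrophobic = continuous && is.finite(mh) && mh > 0,
    n_interior_stations = nrow(p),
    verdict = if (continuous) "continuous tunnel" else "no continuous tunnel"
  )
}

#' Parse a point-mutation string like "G200E"
#' @param x string `<from><residue_number><to>` in 1-letter codes
#' @return `mutation_spec` list: `residue_number`, `from_aa`, `to_aa`
#' @export
mutation_spec <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x))[[1]]
  if (length(m) != 4) stop("cannot parse mutation '", x, "'; expected e.g. 'G200E'")
  structure(list(residue_number = as.integer(m[3]),
                 from_aa = toupper(m[2]), to_aa = toupper(m[4])),
            class = "mutation_spec")
}

# pseudo-CB direction: actual CB if present, else ideal tetrahedral
# construction from backbone N, CA, C (needed for glycine)
sidechain_direction <- function(model, resno) {
  a <- model$atoms[model$atoms$residue_number == resno, , drop = FALSE]
  at <- function(nm) {
    r <- a[a$atom_name == nm, c("x", "y", "z"), drop = FALSE]
    if (nrow(r) == 0) NULL else as.numeric(r[1, ])
  }
  ca <- at("CA")
  if (is.null(ca)) stop("residue ", resno, " has no CA atom")
  cb <- at("CB")
  if (!is.null(cb)) {
    v <- cb - ca
    return(list(ca = ca, dir = v / sqrt(sum(v^2))))
  }
  nN <- at("N"); cC <- at("C")
  if (is.null(nN) || is.null(cC)) {
    stop("residue ", resno, " lacks CB and backbone N/C; cannot place side chain")
  }
  u <- (nN - ca); u <- u / sqrt(sum(u^2))
  v <- (cC - ca); v <- v / sqrt(sum(v^2))
  bis <- -(u + v)
  nb <- sqrt(sum(bis^2))
  if (nb < 1e-8) stop("degenerate backbone geometry at residue ", resno)
  bis <- bis / nb
  perp <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
  np <- sqrt(sum(perp^2))
  if (np < 1e-8) stop("collinear backbone at residue ", resno)
  perp <- perp / np
  # tetrahedral tilt: ~54.75 deg out of the N-CA-C bisector direction
  d <- cos(0.9556) * bis + sin(0.9556) * perp
  list(ca = ca, dir = d / sqrt(sum(d^2)))
}

#' Local tunnel radius change caused by a point substitution
#'
#' The substituted side chain is modelled as a single sphere placed 2.4 A
#' from CA along the CA->CB direction (for glycine, an ideal tetrahedral CB
#' direction is constructed from backbone N, CA, C), with the
#' volume-equivalent radius of the target residue's side chain. Radii are
#' recomputed at stations within `arc_window` arclength of the residue's
#' nearest station, with both the original and substituted residue modelled
#' the same way, so an identity substitution yields exactly zero change.
#'
#' @param model [structure_model()]
#' @param mut [mutation_spec()] or a string like `"G200E"`
#' @param axis [estimate_axis()] output
#' @param shell lining shell passed to [radius_profile()] (default 3)
#' @param arc_window arclength half-window around the residue, Angstrom
#'   (default 15)
#' @return `mutation_report`: data.frame with `s`, `radius_before`,
#'   `radius_after`, `delta_radius` (<= 0 where the substituted sphere
#'   protrudes into the lumen); attributes `mutation`, `sphere_center`,
#'   `sphere_radius`
#' @export
mutation_blockage <- function(model, mut, axis, shell = 3, arc_window = 15) {
  if (is.character(mut)) mut <- mutation_spec(mut)
  a <- model$atoms
  ares <- a[a$residue_number == mut$residue_number, , drop = FALSE]
  if (nrow(ares) == 0) stop("residue ", mut$residue_number, " not in model")
  actual <- aa_three_to_one(ares$residue_name[1])
  if (actual != mut$from_aa) {
    stop("from_aa mismatch at residue ", mut$residue_number, ": model has '",
         actual, "', mutation says '", mut$from_aa,
         "' (numbering drift guard)")
  }
  sc <- sidechain_direction(model, mut$residue_number)
  center <- sc$ca + 2.4 * sc$dir
  r_from <- unname(SIDECHAIN_RADIUS[mut$from_aa])
  r_to <- unname(SIDECHAIN_RADIUS[mut$to_aa])
  if (is.na(r_from) || is.na(r_to)) stop("unknown amino-acid code in mutation")
  # stations near the residue
  P <- as.matrix(axis[, c("x", "y", "z")])
  d_ca <- sqrt(rowSums(sweep(P, 2, sc$ca)^2))
  s0 <- axis$s[which.min(d_ca)]
  near <- abs(axis$s - s0) <= arc_window
  ax_near <- axis[near, , drop = FALSE]
  prof <- radius_profile(model, ax_near, shell = shell)
  d_sphere <- sqrt(rowSums(sweep(as.matrix(ax_near[, c("x", "y", "z")]), 2, center)^2))
  before <- pmax(pmin(prof$radius, d_sphere - r_from), 0)
  after <- pmax(pmin(prof$radius, d_sphere - r_to), 0)
  structure(
    data.frame(s = ax_near$s, radius_before = before, radius_after = after,
               delta_radius = after - before),
    class = c("mutation_report", "data.frame"),
    mutation = mut, sphere_center = center,
    sphere_radius = c(from = r_from, to = r_to),
    nearest_station_s = s0
  )
}
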