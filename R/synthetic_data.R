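# synthetic_data: ground-truthed hollow-tube benchmark structures and
# fragmented/perturbed inputs emulating independent per-fragment predictions.

# uniform random proper rotation via a normalized random quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Generate a hollow helical tube structure with known geometry
#'
#' A residue chain wound helically about a straight axis (the z axis),
#' emulating the rod-and-tunnel architecture of bridge-like lipid transfer
#' proteins as a testable geometry. Each residue carries backbone N, CA, C
#' and (except glycine) a single pseudo-side-chain CB sphere. Residues
#' alternate between lumen-facing (side chain pointing at the axis,
#' identities from `lumen_aa`, hydrophobic by default) and outward-facing
#' (identities from `outer_aa`, charged by default), so the lumen wall is
#' hydrophobic the way a lipid-conduit lining is. Confidence is 90
#' everywhere (pLDDT convention).
#'
#' The innermost atom centers are the lumen-facing CB spheres at
#' `inner_wall_radius` from the axis, so the true open lumen radius is
#' `inner_wall_radius - 1.70` (carbon vdW).
#'
#' @param n_res residues (>= 50)
#' @param length rod length along the axis, Angstrom
#' @param inner_wall_radius distance of lumen-wall atom centers from the
#'   axis, Angstrom (> 2)
#' @param turns helical winding count; `NULL` (default) picks the smallest
#'   winding giving consecutive CA spacing of at least 3.9 A
#' @param lumen_aa,outer_aa 1-letter alphabets for lumen-/outward-facing
#'   residues
#' @param seed integer seed for residue-identity sampling
#' @return list with `model` ([structure_model()]) and `truth`
#'   (`synthetic_truth`: true axis polyline, `lumen_radius`, geometry
#'   parameters, seed)
#' @export
make_tube <- function(n_res = 900, length = 300, inner_wall_radius = 7.7,
                      turns = NULL, lumen_aa = c("I", "L", "V"),
                      outer_aa = c("D", "E", "K", "R"), seed = 1) {
  if (n_res < 50) stop("parameter error: n_res must be >= 50")
  if (length <= 0) stop("parameter error: length must be > 0")
  if (inner_wall_radius <= 2) stop("parameter error: inner_wall_radius must be > 2 A")
  side_len <- 2.4
  r_ca <- inner_wall_radius + side_len
  dz <- length / (n_res - 1)
  spacing_for <- function(k) {
    dt <- 2 * pi * k / (n_res - 1)
    sqrt(dz^2 + (2 * r_ca * sin(dt / 2))^2)
  }
  if (is.null(turns)) {
    # smallest winding with consecutive CA spacing >= 3.9 A (margin over the
    # 3.8 A peptide constraint); 0 when the tube is stretched enough already
    turns <- 0L
    while (spacing_for(turns) < 3.9 && turns < (n_res - 1) %/% 2) {
      turns <- turns + 1L
    }
  }
  dtheta <- 2 * pi * turns / (n_res - 1)
  spacing <- spacing_for(turns)
  if (spacing < 3.8 - 1e-9) {
    stop("parameter error: consecutive CA spacing ", round(spacing, 2),
         " A < 3.8 A; reduce turns or n_res, or lengthen the tube")
  }
  i <- seq_len(n_res)
  theta <- (i - 1) * dtheta
  zc <- (i - 1) * dz
  ca <- cbind(r_ca * cos(theta), r_ca * sin(theta), zc)
  rhat <- cbind(cos(theta), sin(theta), 0)
  tang <- cbind(-r_ca * sin(theta) * dtheta, r_ca * cos(theta) * dtheta,
                rep(dz, n_res))
  tang <- tang / sqrt(rowSums(tang^2))
  lumen <- i %% 2 == 1
  shat <- rhat * ifelse(lumen, -1, 1)
  set.seed(seed)
  aa <- character(n_res)
  aa[lumen] <- sample(lumen_aa, sum(lumen), replace = TRUE)
  aa[!lumen] <- sample(outer_aa, sum(!lumen), replace = TRUE)
  xyz_n <- ca - 1.2 * tang - 0.5 * shat
  xyz_c <- ca + 1.2 * tang - 0.5 * shat
  xyz_cb <- ca + side_len * shat
  has_cb <- aa != "G"
  per_res <- 3L + has_cb
  res_of <- rep(i, per_res)
  name_of <- unlist(lapply(i, function(k) {
    if (has_cb[k]) c("N", "CA", "C", "CB") else c("N", "CA", "C")
  }), use.names = FALSE)
  xyz <- matrix(NA_real_, sum(per_res), 3)
  xyz[name_of == "N", ] <- xyz_n
  xyz[name_of == "CA", ] <- ca
  xyz[name_of == "C", ] <- xyz_c
  xyz[name_of == "CB", ] <- xyz_cb[has_cb, , drop = FALSE]
  at <- data.frame(
    serial = seq_along(res_of),
    atom_name = name_of,
    residue_name = aa_one_to_three(aa)[res_of],
    chain_id = "A",
    residue_number = res_of,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = ifelse(name_of == "N", "N", "C"),
    confidence = 90,
    stringsAsFactors = FALSE
  )
  model <- structure_model(at)
  s_axis <- seq(0, length, by = 2)
  truth <- structure(list(
    axis = data.frame(s = s_axis, x = 0, y = 0, z = s_axis),
    lumen_radius = inner_wall_radius - 1.70,
    length = length, inner_wall_radius = inner_wall_radius,
    turns = turns, ca_radius = r_ca, ca_spacing = spacing,
    sequence = paste(aa, collapse = ""), seed = seed
  ), class = "synthetic_truth")
  list(model = model, truth = truth)
}

#' Fragment a model and perturb each fragment independently
#'
#' The inverse of [assemble()]: cuts the model into the plan's overlapping
#' windows and gives each fragment an independent uniformly random proper
#' rotation, a translation uniform in +/-100 A per axis, and iid Gaussian
#' coordinate noise — emulating independently predicted fragments delivered
#' in arbitrary frames. Per-residue confidence decays linearly from 90 to 50
#' over the terminal `decay_len` residues at each fragment end, mimicking
#' the pLDDT drop at artificial termini that motivates overlapping windows
#' in the first place. All randomness streams from the single `seed`.
#'
#' @param model source [structure_model()]
#' @param plan [plan_fragments()] output covering the model's residue range
#' @param sigma Gaussian noise s.d. per coordinate, Angstrom (default 0)
#' @param seed master integer seed
#' @param conf_high,conf_low interior / terminal confidence (default 90, 50)
#' @param decay_len residues over which confidence decays at each fragment
#'   end (default 50)
#' @return list with `fragments` (list of [structure_model()]) and `truth`
#'   (`synthetic_truth`: exact per-fragment [rigid_transform()]s, `sigma`,
#'   `seed`)
#' @export
fragment_and_perturb <- function(model, plan, sigma = 0, seed = 1,
                                 conf_high = 90, conf_low = 50,
                                 decay_len = 50) {
  rn <- residue_numbers(model)
  iv <- plan$intervals
  if (min(iv$start) < min(rn) || max(iv$end) > max(rn)) {
    stop("plan range [", min(iv$start), ", ", max(iv$end),
         "] exceeds model residues [", min(rn), ", ", max(rn), "]")
  }
  set.seed(seed)
  fragments <- vector("list", nrow(iv))
  transforms <- vector("list", nrow(iv))
  for (i in seq_len(nrow(iv))) {
    R <- random_rotation()
    t <- runif(3, -100, 100)
    xfm <- rigid_transform(R, t)
    frag <- subset_residues(model, iv$start[i], iv$end[i])
    X <- apply_transform(xfm, atom_coords(frag))
    if (sigma > 0) {
      X <- X + matrix(rnorm(base::length(X), 0, sigma), ncol = 3)
    }
    frag <- set_coords(frag, X)
    dist_end <- pmin(frag$atoms$residue_number - iv$start[i],
                     iv$end[i] - frag$atoms$residue_number)
    frag$atoms$confidence <- conf_low +
      (conf_high - conf_low) * pmin(1, dist_end / decay_len)
    fragments[[i]] <- frag
    transforms[[i]] <- xfm
  }
  truth <- structure(list(
    transforms = transforms, sigma = sigma, seed = seed, plan = plan
  ), class = "synthetic_truth")
  list(fragments = fragments, truth = truth)
}
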