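# stitcher: rigid-body superposition on overlap residues and fragment
# splicing into a full-length model.

#' Construct a rigid transform
#'
#' A proper rotation (det = +1, orthonormal to 1e-9) plus translation,
#' applied as `x -> R x + t`.
#'
#' @param R 3x3 rotation matrix
#' @param t length-3 translation (Angstrom)
#' @return object of class `rigid_transform`
#' @export
rigid_transform <- function(R, t = c(0, 0, 0)) {
  R <- as.matrix(R); t <- as.numeric(t)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) {
    stop("rotation matrix is not orthonormal")
  }
  if (abs(det(R) - 1) > 1e-9) {
    stop("rotation matrix is not proper (det != +1); reflections excluded")
  }
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param xfm `rigid_transform`
#' @param X n x 3 coordinate matrix (or a [structure_model()])
#' @return transformed object of the same kind
#' @export
apply_transform <- function(xfm, X) {
  stopifnot(inherits(xfm, "rigid_transform"))
  if (inherits(X, "structure_model")) {
    return(set_coords(X, apply_transform(xfm, atom_coords(X))))
  }
  X <- as.matrix(X)
  sweep(X %*% t(xfm$R), 2, xfm$t, "+")
}

#' Compose two rigid transforms: (a o b)(x) = a(b(x))
#' @param a,b `rigid_transform`s
#' @return `rigid_transform`
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param xfm `rigid_transform`
#' @return `rigid_transform`
#' @export
invert_transform <- function(xfm) {
  rigid_transform(t(xfm$R), as.numeric(-t(xfm$R) %*% xfm$t))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `R Q + t` onto `P` over paired rows. Reflections are excluded by
#' construction (the determinant correction of the SVD solution), so the
#' result is always a physically realizable rigid motion.
#'
#' @param P,Q n x 3 matrices of paired coordinates (Angstrom), n >= 3
#' @return list with `transform` ([rigid_transform()] mapping Q onto P),
#'   `rmsd` (Angstrom) and `n_atoms`
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3) {
    stop("P and Q must be paired n x 3 matrices")
  }
  n <- nrow(P)
  if (n < 3) stop("insufficient points: need n >= 3, got ", n)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Qc, Pc)              # 3x3 cross-covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-30)) {
    warning("near-collinear point set; superposition is ill-conditioned")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cp - as.numeric(R %*% cq)
  xfm <- rigid_transform(R, t)
  resid <- apply_transform(xfm, Q) - P
  list(transform = xfm, rmsd = sqrt(mean(rowSums(resid^2))), n_atoms = n)
}

#' Superpose a moving fragment onto a reference over shared overlap residues
#'
#' Pairs CA atoms by residue number inside the overlap window, requires the
#' one-letter sequences to agree on the shared residues (a mismatch signals
#' numbering drift and is an error), and performs a Kabsch fit on the paired
#' CA coordinates only. CA-only fitting is deliberate: side-chain
#' conformations of independently predicted fragments differ even where the
#' backbone agrees.
#'
#' @param ref reference [structure_model()] (defines the target frame)
#' @param mov moving [structure_model()]
#' @param overlap length-2 vector `(start, end)` of the shared residue window
#' @return `overlap_superposition`: list with `transform` (maps `mov` into
#'   the `ref` frame), `rmsd` (CA RMSD, Angstrom), `n_atoms`, `overlap`
#' @export
superpose_on_overlap <- function(ref, mov, overlap) {
  overlap <- as.integer(overlap)
  stopifnot(length(overlap) == 2)
  Pr <- ca_coords(ref); Pm <- ca_coords(mov)
  shared <- intersect(rownames(Pr), rownames(Pm))
  shared <- shared[as.integer(shared) >= overlap[1] & as.integer(shared) <= overlap[2]]
  if (length(shared) < 3) {
    stop("fewer than 3 shared CA residues in overlap [",
         overlap[1], ", ", overlap[2], "]")
  }
  shared <- as.character(sort(as.integer(shared)))
  # sequence agreement on shared residues
  seq_of <- function(m, res) {
    a <- m$atoms[!duplicated(m$atoms$residue_number), , drop = FALSE]
    aa_three_to_one(a$residue_name[match(as.integer(res), a$residue_number)])
  }
  sr <- seq_of(ref, shared); sm <- seq_of(mov, shared)
  bad <- which(sr != sm)
  if (length(bad) > 0) {
    stop("sequence mismatch in overlap at residue ", shared[bad[1]],
         ": '", sr[bad[1]], "' vs '", sm[bad[1]], "'")
  }
  fit <- kabsch_superpose(Pr[shared, , drop = FALSE], Pm[shared, , drop = FALSE])
  structure(
    list(transform = fit$transform, rmsd = fit$rmsd, n_atoms = fit$n_atoms,
         overlap = c(start = overlap[1], end = overlap[2])),
    class = "overlap_superposition"
  )
}

# crossover residue for one junction
choose_crossover <- function(rule, overlap, left, right, trim = 0) {
  s <- overlap[1] + trim; e <- overlap[2] - trim
  if (rule == "midpoint") return(as.integer(floor((s + e) / 2)))
  # max_confidence: c maximizing min(mean left conf on [s, c],
  #                                  mean right conf on (c, e])
  res_conf <- function(m) {
    a <- m$atoms[m$atoms$residue_number >= s & m$atoms$residue_number <= e, ]
    tapply(a$confidence, a$residue_number, mean)
  }
  lc <- res_conf(left); rc <- res_conf(right)
  res <- sort(unique(as.integer(names(lc))))
  cand <- res[res < e]
  if (length(cand) == 0) return(as.integer(floor((s + e) / 2)))
  score <- vapply(cand, function(cc) {
    ml <- mean(lc[as.integer(names(lc)) <= cc])
    mr <- mean(rc[as.integer(names(rc)) > cc])
    min(ml, mr)
  }, numeric(1))
  as.integer(cand[which.max(score)])   # first argmax on ties
}

#' Assemble overlapping fragments into a full-length model
#'
#' Fragment 1 anchors the global frame. Each subsequent fragment is
#' superposed onto the growing assembly over its planned overlap
#' ([superpose_on_overlap()]), then spliced at a single crossover residue
#' `c`: residues `<= c` come from the assembly (left), residues `> c` from
#' the incoming fragment. `midpoint` takes the centre of the overlap;
#' `max_confidence` picks `c` maximizing the worse of the two sides' mean
#' confidence, exploiting the fact that predictor confidence decays toward
#' artificial fragment termini.
#'
#' @param fragments list of [structure_model()], one per plan interval, in
#'   order
#' @param plan [plan_fragments()] output matching the fragments
#' @param splice_rule `"midpoint"` (default) or `"max_confidence"`
#' @param trim_overlap residues dropped from each end of every overlap before
#'   fitting and crossover selection (default 0: use the full overlap)
#' @param rmsd_warn junction CA-RMSD (Angstrom) above which a warning is
#'   emitted; assembly continues (default 5)
#' @param clash_cutoff distance (Angstrom) used for the junction clash count
#'   in the report (default 2)
#' @return list with `model` (the assembled [structure_model()], residues
#'   exactly `1..L`, each from one fragment) and `report`
#'   (`stitch_report`: per-junction RMSD/crossover, junction clash count —
#'   clashing atom pairs drawn from two different source fragments — and
#'   totals)
#' @export
assemble <- function(fragments, plan, splice_rule = c("midpoint", "max_confidence"),
                     trim_overlap = 0, rmsd_warn = 5, clash_cutoff = 2.0) {
  splice_rule <- match.arg(splice_rule)
  iv <- plan$intervals
  if (length(fragments) != nrow(iv)) {
    stop("missing fragment: plan has ", nrow(iv), " interval(s), got ",
         length(fragments), " fragment(s)")
  }
  for (i in seq_along(fragments)) {
    rn <- residue_numbers(fragments[[i]])
    if (min(rn) > iv$start[i] || max(rn) < iv$end[i]) {
      stop("fragment ", i, " does not cover its plan interval [",
           iv$start[i], ", ", iv$end[i], "]")
    }
  }
  assembled <- fragments[[1]]
  source_frag <- rep(1L, nrow(assembled$atoms))
  junctions <- NULL
  if (length(fragments) > 1) {
    for (i in 2:length(fragments)) {
      ov <- plan_overlap_interval(plan, i)
      ov_fit <- c(ov[1] + trim_overlap, ov[2] - trim_overlap)
      sup <- superpose_on_overlap(assembled, fragments[[i]], ov_fit)
      if (sup$rmsd > rmsd_warn) {
        warning(sprintf("junction %d overlap RMSD %.2f A exceeds %.1f A",
                        i - 1, sup$rmsd, rmsd_warn))
      }
      frag_i <- apply_transform(sup$transform, fragments[[i]])
      cross <- choose_crossover(splice_rule, ov, assembled, frag_i, trim_overlap)
      keep_left <- assembled$atoms$residue_number <= cross
      keep_right <- frag_i$atoms$residue_number > cross
      source_frag <- c(source_frag[keep_left], rep(i, sum(keep_right)))
      assembled <- structure_model(rbind(
        assembled$atoms[keep_left, , drop = FALSE],
        frag_i$atoms[keep_right, , drop = FALSE]
      ))
      junctions <- rbind(junctions, data.frame(
        junction = i - 1L, overlap_start = ov[1], overlap_end = ov[2],
        rmsd = sup$rmsd, n_atoms = sup$n_atoms, crossover = cross
      ))
    }
  }
  rownames(junctions) <- NULL
  clashes <- clash_report(assembled, cutoff = clash_cutoff)
  cross_frag <- if (nrow(clashes) > 0) {
    sum(source_frag[clashes$i] != source_frag[clashes$j])
  } else 0L
  rn <- residue_numbers(assembled)
  report <- structure(list(
    junctions = junctions,
    clash_count = as.integer(cross_frag),
    clash_cutoff = clash_cutoff,
    total_residues = length(rn),
    residue_range = range(rn),
    splice_rule = splice_rule
  ), class = "stitch_report")
  if (length(rn) != plan$L || !identical(rn, seq_len(plan$L))) {
    warning("assembled model residues are not exactly 1..L of the plan")
  }
  list(model = assembled, report = report)
}

#' @export
print.stitch_report <- function(x, ...) {
  cat(sprintf("<stitch_report> %d residues, %d junction(s), %d junction clash(es) at %.1f A\n",
              x$total_residues,
              if (is.null(x$junctions)) 0L else nrow(x$junctions),
              x$clash_count, x$clash_cutoff))
  if (!is.null(x$junctions)) print(x$junctions, row.names = FALSE)
  invisible(x)
}

#' Steric clash report
#'
#' All atom pairs closer than `cutoff`, excluding pairs fewer than 3 residues
#' apart in sequence on the same chain (bonded and near-bonded atoms).
#' Neighbour search uses a uniform grid (cell list) with cell size `cutoff`,
#' so cost is near-linear in atom count.
#'
#' @param model [structure_model()]
#' @param cutoff distance threshold, Angstrom (default 2)
#' @return data.frame with atom row indices `i`,`j`, serials, residue
#'   numbers and `distance`; zero rows when clash-free
#' @export
clash_report <- function(model, cutoff = 2.0) {
  a <- model$atoms
  X <- atom_coords(model)
  n <- nrow(X)
  empty <- data.frame(i = integer(0), j = integer(0),
                      serial_i = integer(0), serial_j = integer(0),
                      resno_i = integer(0), resno_j = integer(0),
                      distance = numeric(0))
  if (n < 2) return(empty)
  cell <- floor(sweep(X, 2, apply(X, 2, min)) / cutoff)
  key <- cell[, 1] + 100000 * (cell[, 2] + 100000 * cell[, 3])
  groups <- split(seq_len(n), key)
  cell_of <- cell[match(as.numeric(names(groups)), key), , drop = FALSE]
  # half-shell of neighbour offsets (13 of 26) + same cell
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[with(offs, dz > 0 | (dz == 0 & (dy > 0 | (dy == 0 & dx > 0)))), ]
  lookup <- new.env(hash = TRUE)
  for (g in seq_along(groups)) {
    assign(as.character(names(groups)[g]), g, envir = lookup)
  }
  res <- list()
  add_pairs <- function(ii, jj) {
    if (length(ii) == 0 || length(jj) == 0) return()
    D <- outer(rowSums(X[ii, , drop = FALSE]^2), rowSums(X[jj, , drop = FALSE]^2), "+") -
      2 * X[ii, , drop = FALSE] %*% t(X[jj, , drop = FALSE])
    hit <- which(D < cutoff^2, arr.ind = TRUE)
    if (nrow(hit) == 0) return()
    i <- ii[hit[, 1]]; j <- jj[hit[, 2]]
    if (identical(ii, jj)) { keep <- i < j; i <- i[keep]; j <- j[keep] }
    if (length(i) == 0) return()
    same_chain <- a$chain_id[i] == a$chain_id[j]
    near <- same_chain & abs(a$residue_number[i] - a$residue_number[j]) < 3
    i2 <- i[!near]; j2 <- j[!near]
    if (length(i2) == 0) return()
    d <- sqrt(rowSums((X[i2, , drop = FALSE] - X[j2, , drop = FALSE])^2))
    res[[length(res) + 1L]] <<- data.frame(i = i2, j = j2, distance = d)
  }
  for (g in seq_along(groups)) {
    ii <- groups[[g]]
    add_pairs(ii, ii)
    for (o in seq_len(nrow(offs))) {
      nb <- cell_of[g, ] + as.numeric(offs[o, ])
      nb_key <- as.character(nb[1] + 100000 * (nb[2] + 100000 * nb[3]))
      h <- mget(nb_key, envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(h)) add_pairs(ii, groups[[h]])
    }
  }
  if (length(res) == 0) return(empty)
  out <- do.call(rbind, res)
  swap <- out$i > out$j
  tmp <- out$i[swap]; out$i[swap] <- out$j[swap]; out$j[swap] <- tmp
  out <- out[order(out$i, out$j), , drop = FALSE]
  data.frame(
    i = out$i, j = out$j,
    serial_i = a$serial[out$i], serial_j = a$serial[out$j],
    resno_i = a$residue_number[out$i], resno_j = a$residue_number[out$j],
    distance = out$distance, row.names = NULL
  )
}

#' All-atom RMSD between two models after optimal superposition
#'
#' Convenience metric for benchmarking an assembly against ground truth:
#' pairs atoms by (chain, residue number, atom name), Kabsch-superposes the
#' second model onto the first, and returns the residual RMSD. The global
#' frame of an assembly is arbitrary (it inherits the anchor fragment's
#' frame), so comparison must be up to a rigid motion.
#'
#' @param model,reference [structure_model()]s
#' @param atoms `"all"` or `"CA"`
#' @return RMSD in Angstrom
#' @export
rmsd_to_reference <- function(model, reference, atoms = c("all", "CA")) {
  atoms <- match.arg(atoms)
  key <- function(m) paste(m$atoms$chain_id, m$atoms$residue_number, m$atoms$atom_name)
  ka <- key(model); kb <- key(reference)
  shared <- intersect(ka, kb)
  if (atoms == "CA") shared <- shared[grepl(" CA$", shared)]
  if (length(shared) < 3) stop("fewer than 3 shared atoms")
  A <- atom_coords(model)[match(shared, ka), , drop = FALSE]
  B <- atom_coords(reference)[match(shared, kb), , drop = FALSE]
  kabsch_superpose(B, A)$rmsd
}
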