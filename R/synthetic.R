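# Parametric generator of labelled synthetic C-alpha geometries: solenoids of
# the three classes, compact globular decoys, and composite chains. The
# generator models C-alpha geometry only — no side chains, no energies — and
# is the corpus every other module is trained and tested on.
#
# Construction of a solenoid: a cross-section path in the xy-plane is
# traversed exactly once per repeat while z advances linearly
# (rise_per_repeat per repeat), giving a straight stack with exact
# translational repeat symmetry. The stack is then bent so its axis follows
# a circle of radius superhelix_radius; the bend maps the translation between
# repeats to a rotation, so repeats remain exactly congruent rigid bodies:
# repeat k occupies the angular sector k * rise_per_repeat / superhelix_radius.
# Class-distinctive local geometry: beta repeats walk the path at extended
# strand spacing (3.5 A/residue); alpha repeats advance at helix rise
# (1.5 A/residue) with an ideal-helix wave (radius 2.3 A, ~100 deg/residue)
# wound about the path; alpha/beta repeats have one helical and one extended
# segment per repeat.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Solenoid geometry parameters
#'
#' @param class_id Solenoid class: 1 (beta), 2 (alpha/beta), 3 (alpha).
#' @param repeat_length Residues per repeat unit. Defaults: 18 (beta),
#'   25 (alpha/beta), 34 (alpha).
#' @param n_repeats Number of stacked repeats (>= 3; a solenoid needs
#'   multiple turns).
#' @param superhelix_radius Bend radius of the solenoid axis in Angstroms;
#'   larger values give straighter solenoids. Defaults: 250 (beta),
#'   140 (alpha/beta), 90 (alpha).
#' @param rise_per_repeat Axial stacking distance between consecutive repeats
#'   in Angstroms. Defaults: 4.8 (beta), 7.5 (alpha/beta), 9.5 (alpha).
#' @param jitter_sd Standard deviation (Angstroms) of isotropic Gaussian
#'   coordinate noise; consecutive C-alpha distances are clipped back into
#'   [2.9, 4.1] A afterwards.
#' @param seed Integer seed; identical seeds give identical chains.
#' @param local Local-style constants: helix rise and turn per residue,
#'   helix radius, and extended-strand spacing.
#'
#' @return An object of class `solenoid_geometry`.
#' @export
solenoid_geometry <- function(class_id, repeat_length = NULL, n_repeats = 6L,
                              superhelix_radius = NULL, rise_per_repeat = NULL,
                              jitter_sd = 0.3, seed = 1L,
                              local = list(helix_rise = 1.5,
                                           helix_turn_deg = 100,
                                           helix_radius = 2.3,
                                           strand_spacing = 3.5)) {
  if (!class_id %in% 1:3) stop("class_id must be 1, 2 or 3")
  if (missing(local) && class_id == 2L) local$helix_radius <- 2.0
  defaults <- list(`1` = c(18L, 250, 4.8), `2` = c(25L, 140, 7.5),
                   `3` = c(34L, 90, 9.5))[[as.character(class_id)]]
  if (is.null(repeat_length)) repeat_length <- defaults[1]
  if (is.null(superhelix_radius)) superhelix_radius <- defaults[2]
  if (is.null(rise_per_repeat)) rise_per_repeat <- defaults[3]
  repeat_length <- as.integer(repeat_length)
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 3L) stop("n_repeats must be >= 3 (stacked turns)")
  if (repeat_length < 8L) stop("repeat_length must be >= 8")
  if (superhelix_radius <= 0 || rise_per_repeat <= 0)
    stop("superhelix_radius and rise_per_repeat must be positive")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  structure(list(class_id = as.integer(class_id),
                 repeat_length = repeat_length, n_repeats = n_repeats,
                 superhelix_radius = superhelix_radius,
                 rise_per_repeat = rise_per_repeat, jitter_sd = jitter_sd,
                 seed = as.integer(seed), local = local),
            class = "solenoid_geometry")
}

# Arc-length increments of one repeat along the cross-section path, plus a
# flag for which residues carry the helical wave. The increments sum to the
# path perimeter, so the path wraps exactly once per repeat.
repeat_arc_pattern <- function(geom) {
  L <- geom$repeat_length
  lo <- geom$local
  if (geom$class_id == 1L) {
    list(ds = rep(lo$strand_spacing, L), helical = rep(FALSE, L))
  } else if (geom$class_id == 3L) {
    list(ds = rep(lo$helix_rise, L), helical = rep(TRUE, L))
  } else {
    m_h <- round(0.6 * L)
    ds <- c(2.4, rep(lo$helix_rise, m_h - 1L), 2.4,
            rep(lo$strand_spacing, L - m_h - 1L))
    list(ds = ds, helical = c(rep(TRUE, m_h), rep(FALSE, L - m_h)))
  }
}

# Cross-section path position and in-plane normal at arc position s.
# Beta solenoids use an equilateral-triangle path (their cross-sections are
# polygonal); the other classes use a circle.
path_point <- function(s, perimeter, triangle) {
  if (!triangle) {
    r <- perimeter / (2 * pi)
    th <- s / r
    list(p = c(r * cos(th), r * sin(th)), n = c(cos(th), sin(th)))
  } else {
    side <- perimeter / 3
    s <- s %% perimeter
    k <- pmin(floor(s / side), 2)
    f <- s / side - k
    R_tri <- side / sqrt(3)
    ang <- pi / 2 + k * 2 * pi / 3
    v0 <- c(R_tri * cos(ang), R_tri * sin(ang))
    v1 <- c(R_tri * cos(ang + 2 * pi / 3), R_tri * sin(ang + 2 * pi / 3))
    p <- v0 + f * (v1 - v0)
    edge <- (v1 - v0) / sqrt(sum((v1 - v0)^2))
    list(p = p, n = c(edge[2], -edge[1]))
  }
}

# Clip consecutive C-alpha steps into [2.9, 4.1] A by rescaling each
# out-of-range step and shifting the downstream chain, which preserves all
# later step vectors.
clip_steps <- function(xyz, lo = 2.95, hi = 4.05) {
  n <- nrow(xyz)
  for (i in 2:n) {
    v <- xyz[i, ] - xyz[i - 1L, ]
    len <- sqrt(sum(v^2))
    if (len < lo || len > hi) {
      target <- min(max(len, lo), hi)
      delta <- v * (target / len - 1)
      xyz[i:n, ] <- sweep(xyz[i:n, , drop = FALSE], 2, delta, `+`)
    }
  }
  xyz
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Random amino-acid sequence; solenoid repeats share a template with 10%
# per-position mutations so repeat alignments show consensus positions.
solenoid_sequence <- function(L, n_repeats) {
  template <- sample(AA1, L, replace = TRUE)
  unlist(lapply(seq_len(n_repeats), function(k) {
    mut <- runif(L) < 0.1
    s <- template
    s[mut] <- sample(AA1, sum(mut), replace = TRUE)
    s
  }))
}

#' Generate a synthetic solenoid chain with ground-truth labels
#'
#' Lays a C-alpha trace on a superhelical path with exactly congruent repeat
#' units (see the package vignette for the construction). All residues carry
#' the solenoid class label. With `jitter_sd = 0` repeats are exact rigid
#' copies of each other; with jitter, consecutive C-alpha distances are
#' clipped back into [2.9, 4.1] A.
#'
#' @param geom A [solenoid_geometry()].
#' @return A list with elements `chain` ([chain_structure()]), `labels`
#'   (integer vector), and `repeat_boundaries` (1-based register start index
#'   of each repeat).
#' @export
make_solenoid <- function(geom) {
  stopifnot(inherits(geom, "solenoid_geometry"))
  set.seed(geom$seed)
  L <- geom$repeat_length
  R <- geom$n_repeats
  n <- L * R
  pat <- repeat_arc_pattern(geom)
  perimeter <- sum(pat$ds)
  lo <- geom$local
  omega <- 2 * pi * max(1, round(L * lo$helix_turn_deg / 360)) / L
  triangle <- geom$class_id == 1L
  rc <- perimeter / (2 * pi)
  xyz <- matrix(0, n, 3)
  s <- 0
  for (t in seq_len(n)) {
    j <- (t - 1L) %% L + 1L               # index within repeat
    if (t > 1L) s <- s + pat$ds[j]
    pp <- path_point(s, perimeter, triangle)
    z <- geom$rise_per_repeat * (t - 1) / L
    xy <- pp$p
    if (pat$helical[j]) {
      # the -s/rc term parallel-transports the wave phase against the
      # rotation of the path normal, keeping the local helix ideal; it
      # shifts by exactly -2*pi per repeat, so periodicity is preserved
      phase <- omega * (t - 1) - s / rc
      xy <- xy + lo$helix_radius * cos(phase) * pp$n
      z <- z + lo$helix_radius * sin(phase)
    }
    xyz[t, ] <- c(xy, z)
  }
  # bend the stack axis around a circle: z-translation between repeats
  # becomes a rotation, preserving exact repeat congruence
  Rs <- geom$superhelix_radius
  th <- xyz[, 3] / Rs
  xyz <- cbind((Rs + xyz[, 1]) * cos(th), (Rs + xyz[, 1]) * sin(th), xyz[, 2])
  if (geom$jitter_sd > 0)
    xyz <- xyz + matrix(rnorm(3 * n, sd = geom$jitter_sd), n, 3)
  # Step clipping rescales out-of-range steps and rigidly shifts the
  # downstream chain. On the jitter-free construction the corrections are
  # rotated copies of each other across repeats, so congruence survives.
  xyz <- clip_steps(xyz)
  steps <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  if (any(steps < 2.9 | steps > 4.1))
    stop("geometry violates the consecutive C-alpha distance invariant")
  seq1 <- solenoid_sequence(L, R)
  chain <- chain_structure("A", seq_len(n), rep("", n), bio3d::aa123(seq1),
                           xyz, rep(TRUE, n))
  list(chain = chain, labels = rep(geom$class_id, n),
       repeat_boundaries = (seq_len(R) - 1L) * L + 1L)
}

#' Generate a compact globular decoy chain (all labels 0)
#'
#' A self-avoiding C-alpha walk confined to a sphere of radius proportional
#' to n^(1/3), built from randomly oriented stretches of ideal helix,
#' extended strand and coil of random aperiodic lengths. Consecutive
#' distances lie in [3.6, 4.0] A; non-neighbour pairs are at least 3.0 A
#' apart; there is no repeated banding pattern by construction.
#'
#' @param n Number of residues (>= 10).
#' @param seed Integer seed.
#' @return A list with `chain` and `labels` (all 0).
#' @export
make_globular_decoy <- function(n, seed = 1L) {
  n <- as.integer(n)
  if (n < 10L) stop("decoy needs n >= 10")
  set.seed(seed)
  rmax <- 3.2 * n^(1 / 3)
  lo <- list(helix_rise = 1.5, helix_radius = 2.3, omega = 100 * pi / 180)
  pts <- matrix(0, n, 3)
  i <- 1L
  seg <- NULL
  backtracks <- 0L
  new_segment <- function(p) {
    type <- sample(c("helix", "strand", "coil"), 1, prob = c(0.4, 0.3, 0.3))
    len <- switch(type, helix = sample(6:14, 1), strand = sample(5:10, 1),
                  coil = sample(3:6, 1))
    d <- rnorm(3)
    if (sqrt(sum(p^2)) > 0.6 * rmax)  # steer back toward the centre
      d <- d - 1.2 * p / sqrt(sum(p^2))
    d <- d / sqrt(sum(d^2))
    u <- rnorm(3); u <- u - sum(u * d) * d; u <- u / sqrt(sum(u^2))
    v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
           d[1] * u[2] - d[2] * u[1])
    list(type = type, len = len, done = 0L, d = d, u = u, v = v,
         base = p - lo$helix_radius * u, start = p)
  }
  propose <- function(p, seg) {
    k <- seg$done + 1L
    switch(seg$type,
      helix = seg$base + lo$helix_rise * k * seg$d +
        lo$helix_radius * (cos(k * lo$omega) * seg$u +
                             sin(k * lo$omega) * seg$v),
      strand = seg$start + 3.6 * k * seg$d +
        (k %% 2L) * 1.0 * seg$u,
      coil = p + 3.8 * seg$d)
  }
  while (i < n) {
    if (is.null(seg) || seg$done >= seg$len) seg <- new_segment(pts[i, ])
    ok <- FALSE
    for (try in 1:40) {
      cand <- propose(pts[i, ], seg)
      clear <- i < 2L ||
        min(sqrt(rowSums(sweep(pts[seq_len(i - 1L), , drop = FALSE], 2,
                               cand)^2))) >= 3.0
      if (clear && sqrt(sum(cand^2)) <= rmax) { ok <- TRUE; break }
      seg <- new_segment(pts[i, ])   # re-orient and retry
      seg$len <- max(1L, seg$len - 1L)
    }
    if (!ok) {
      backtracks <- backtracks + 1L
      if (backtracks %% 20L == 0L) rmax <- rmax * 1.05
      i <- max(1L, i - 3L)
      seg <- NULL
      next
    }
    if (seg$type == "coil") seg$d <- {  # fresh direction each coil step
      d <- rnorm(3); d / sqrt(sum(d^2))
    }
    seg$done <- seg$done + 1L
    i <- i + 1L
    pts[i, ] <- cand
  }
  seq1 <- sample(AA1, n, replace = TRUE)
  chain <- chain_structure("A", seq_len(n), rep("", n), bio3d::aa123(seq1),
                           pts, rep(TRUE, n))
  list(chain = chain, labels = rep(0L, n))
}

#' Generate a composite chain: globular cap + solenoid core + globular tail
#'
#' Exercises per-residue segmentation: labels are 0 over the caps and the
#' solenoid class over the core, with exact boundaries at the construction
#' joins. Optionally introduces one register gap (a run of absent residues,
#' label 4) to exercise chain-discontinuity handling.
#'
#' @param cap_n,tail_n Residues in the N- and C-terminal globular caps.
#' @param geom [solenoid_geometry()] of the core.
#' @param seed Integer seed for the caps, placement and gap position.
#' @param gap If `TRUE`, a run of 3 register positions (drawn away from the
#'   termini) is marked absent.
#' @return A list with `chain`, `labels`, and `boundaries` (first and last
#'   register index of the solenoid core).
#' @export
make_composite <- function(cap_n, geom, tail_n, seed = 1L, gap = FALSE) {
  stopifnot(cap_n >= 10, tail_n >= 10)
  sol <- make_solenoid(geom)
  set.seed(seed)
  cap <- make_globular_decoy(cap_n, seed = sample.int(2^31 - 1, 1))
  tail <- make_globular_decoy(tail_n, seed = sample.int(2^31 - 1, 1))
  cap_xyz <- chain_xyz(cap$chain)
  sol_xyz <- chain_xyz(sol$chain) %*% random_rotation()
  cap_end <- cap_xyz[nrow(cap_xyz), ]
  dir1 <- cap_end - colMeans(cap_xyz)
  dir1 <- dir1 / max(sqrt(sum(dir1^2)), 1e-9)
  sol_xyz <- sweep(sol_xyz, 2, sol_xyz[1, ] - (cap_end + 3.8 * dir1), `-`)
  sol_end <- sol_xyz[nrow(sol_xyz), ]
  dir2 <- sol_end - colMeans(sol_xyz)
  dir2 <- dir2 / max(sqrt(sum(dir2^2)), 1e-9)
  tail_xyz <- chain_xyz(tail$chain)
  tail_xyz <- sweep(tail_xyz, 2, tail_xyz[1, ] - (sol_end + 3.8 * dir2), `-`)
  xyz <- rbind(cap_xyz, sol_xyz, tail_xyz)
  n <- nrow(xyz)
  resid <- c(cap$chain$residues$resid, sol$chain$residues$resid,
             tail$chain$residues$resid)
  labels <- c(cap$labels, sol$labels, tail$labels)
  present <- rep(TRUE, n)
  if (gap) {
    g0 <- sample(5:(n - 8L), 1L)
    present[g0:(g0 + 2L)] <- FALSE
    xyz[g0:(g0 + 2L), ] <- NA_real_
    labels[g0:(g0 + 2L)] <- 4L
  }
  chain <- chain_structure("A", seq_len(n), rep("", n), resid, xyz, present)
  list(chain = chain, labels = labels,
       boundaries = c(cap_n + 1L, cap_n + chain_length(sol$chain)))
}

#' Generate a labelled synthetic corpus with a manifest
#'
#' Produces `counts[1]` globular decoys and, for each solenoid class,
#' composite chains (globular caps flanking a solenoid core) with geometries
#' randomised within the generator's parameter ranges: repeat length 15-25
#' (beta), 20-30 (alpha/beta), 30-40 (alpha); 4-12 repeats; coordinate
#' jitter 0.2-0.6 A; caps of 20-60 residues; 25% of composites carry one
#' register gap. The manifest records every seed and parameter, and an 80:20
#' train:validation split drawn with a seed derived from the master seed.
#'
#' @param counts Integer vector of length 4: structures per category in the
#'   order (non-solenoid, beta, alpha/beta, alpha).
#' @param seed Master seed; everything (geometries, sub-seeds, split) is a
#'   deterministic function of it.
#' @return An object of class `solseg_corpus`: a list with `structures`
#'   (named list of `list(chain, labels)`) and `manifest` (data frame).
#' @export
make_corpus <- function(counts, seed = 1L) {
  stopifnot(length(counts) == 4, all(counts >= 0))
  counts <- as.integer(counts)
  set.seed(seed)
  cats <- c("decoy", "beta", "alphabeta", "alpha")
  rl_range <- list(beta = c(15, 25), alphabeta = c(20, 30), alpha = c(30, 40))
  structures <- list()
  rows <- list()
  for (ci in 1:4) {
    for (k in seq_len(counts[ci])) {
      id <- sprintf("%s_%03d", cats[ci], k)
      s <- sample.int(2^31 - 1, 1)
      if (ci == 1L) {
        nres <- sample(80:250, 1)
        entry <- make_globular_decoy(nres, seed = s)
        rows[[id]] <- data.frame(id = id, category = cats[ci], class_id = 0L,
                                 seed = s, n_residues = chain_length(entry$chain),
                                 repeat_length = NA_integer_,
                                 n_repeats = NA_integer_, jitter_sd = NA_real_,
                                 cap_n = NA_integer_, tail_n = NA_integer_,
                                 gap = FALSE)
      } else {
        rng <- rl_range[[cats[ci]]]
        rl <- sample(rng[1]:rng[2], 1)
        nrep <- sample(4:12, 1)
        jit <- runif(1, 0.2, 0.6)
        capn <- sample(20:60, 1)
        tailn <- sample(20:60, 1)
        gap <- runif(1) < 0.25
        geom <- solenoid_geometry(ci - 1L, repeat_length = rl,
                                  n_repeats = nrep, jitter_sd = jit, seed = s)
        entry <- make_composite(capn, geom, tailn,
                                seed = sample.int(2^31 - 1, 1), gap = gap)
        rows[[id]] <- data.frame(id = id, category = cats[ci],
                                 class_id = ci - 1L, seed = s,
                                 n_residues = chain_length(entry$chain),
                                 repeat_length = rl, n_repeats = nrep,
                                 jitter_sd = jit, cap_n = capn, tail_n = tailn,
                                 gap = gap)
      }
      structures[[id]] <- entry[c("chain", "labels")]
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  split_seed <- sample.int(2^31 - 1, 1)
  set.seed(split_seed)
  n <- nrow(manifest)
  val <- sample(n, max(1L, round(0.2 * n)))
  manifest$split <- ifelse(seq_len(n) %in% val, "validation", "train")
  manifest$split_seed <- split_seed
  structure(list(structures = structures, manifest = manifest),
            class = "solseg_corpus")
}

#' @export
print.solseg_corpus <- function(x, ...) {
  cat(sprintf("<solseg_corpus> %d structures (%s)\n", nrow(x$manifest),
              paste(sprintf("%s: %d", names(table(x$manifest$category)),
                            table(x$manifest$category)), collapse = ", ")))
  invisible(x)
}

#' Write a corpus to disk as PDB files, label TSVs and a JSON manifest
#'
#' @param corpus A [make_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(corpus$structures)) {
    entry <- corpus$structures[[id]]
    write_chain_pdb(entry$chain, file.path(dir, paste0(id, ".pdb")))
    write_labels(entry$labels, entry$chain, file.path(dir, paste0(id, ".tsv")))
  }
  jsonlite::write_json(corpus$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
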