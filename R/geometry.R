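# Arterial-tree geometries: synthetic generation, CSV round-trip,
# validation, and discretization into the form the engine consumes.
#
# A geometry is a data.frame with one row per segment and the columns
#   id, parent_id, length_cm, area_prox_cm2, area_dist_cm2,
#   p0_mmhg, p1_mmhg, visc_coeff, terminal_r1, terminal_r2, terminal_ct
# (terminal fields NA for internal segments).  parent_id 0 marks the root.

.GEOM_COLS <- c("id", "parent_id", "length_cm", "area_prox_cm2",
                "area_dist_cm2", "p0_mmhg", "p1_mmhg", "visc_coeff",
                "terminal_r1", "terminal_r2", "terminal_ct")

# fractional compliance (dA/dP)/A at pressure pref for the arctangent law,
# per mmHg; depends only on (p0, p1)
.kappa <- function(p1, p0, pref = 100) {
  u <- (pref - p0) / p1
  1 / ((0.5 + atan(u) / pi) * pi * p1 * (1 + u^2))
}

# solve the width pressure p1 (stiff branch) giving a target fractional
# compliance at pref; the arctangent law has a maximum attainable
# compliance for fixed p0, reported when the target is infeasible
.solve_p1 <- function(kappa_target, p0, pref = 100) {
  f <- function(lp) .kappa(10^lp, p0, pref)
  opt <- optimize(f, c(-2, 5), maximum = TRUE)
  if (kappa_target > opt$objective)
    stop(sprintf(paste0("compliance target infeasible for the arctangent ",
                        "wall law: requested %.3g/mmHg exceeds the maximum ",
                        "%.3g/mmHg attainable with p0 = %g mmHg"),
                 kappa_target, opt$objective, p0))
  uniroot(function(lp) f(lp) - kappa_target,
          lower = opt$maximum, upper = 5, tol = 1e-12)$root -> lp
  10^lp
}

# p1 from a target pulse-wave speed (cm/s) at pref, given blood density
.p1_from_wave_speed <- function(c_ref, p0, pref = 100, rho = 1.06) {
  kappa <- .MMHG / (rho * c_ref^2)   # per mmHg
  .solve_p1(kappa, p0, pref)
}

#' Generate a synthetic systemic arterial tree
#'
#' Builds a connected, acyclic tree emulating the human systemic
#' circulation: a tapering aortic trunk, the major branches (carotids,
#' subclavian/brachial, celiac, mesenteric, renal, iliac/femoral paths),
#' reference wave speeds rising distally, and terminal three-element
#' Windkessel elements whose aggregate resistance and compliance land in
#' the physiological range (scalable with [scale_afterload()]).  The
#' geometry is synthetic (not patient- or atlas-derived): branch
#' dimensions are plausible textbook values with optional seeded jitter.
#'
#' `n_segments = 103` subdivides the 24-segment skeleton to emulate the
#' granularity of full-body 1D models; the physics is unchanged.
#'
#' @param n_segments 24 (default) or 103.
#' @param seed Integer seed for the jitter (deterministic output).
#' @param jitter Relative s.d. of the multiplicative jitter applied to
#'   lengths and areas (0 disables).
#' @param p0 Inflection pressure of the wall law, mmHg (shared).
#' @param rho Blood density used to convert wave speeds, g/cm^3.
#' @return A `data.frame` of class `av_tree`.
#' @examples
#' tree <- synthetic_tree(24, seed = 7)
#' aggregate_afterload(tree)
#' @export
synthetic_tree <- function(n_segments = 24, seed = 7, jitter = 0.02,
                           p0 = 80, rho = 1.06) {
  if (!n_segments %in% c(24, 103))
    stop("packaged blueprints provide 24 or 103 segments")
  base <- data.frame(
    name = c("asc_aorta", "arch_a", "arch_b", "thoracic_aorta_a",
             "thoracic_aorta_b", "abdominal_aorta_a", "abdominal_aorta_b",
             "abdominal_aorta_c", "innominate", "r_carotid", "r_brachial",
             "l_carotid", "l_subclavian", "l_brachial", "intercostal",
             "celiac", "sup_mesenteric", "r_renal", "l_renal",
             "inf_mesenteric", "r_iliac", "l_iliac", "r_femoral",
             "l_femoral"),
    parent = c(0, 1, 2, 3, 4, 5, 6, 7, 1, 9, 9, 2, 3, 13, 4, 5, 5, 6, 6,
               7, 8, 8, 21, 22),
    len   = c(4, 3, 3, 5, 10, 5, 8, 6, 3.5, 18, 45, 18, 3.5, 45, 6, 5, 7,
              4, 4, 7, 9, 9, 42, 42),
    aprox = c(5.30, 4.80, 4.30, 3.80, 3.20, 2.40, 2.00, 1.60, 1.20, 0.50,
              0.45, 0.50, 0.80, 0.45, 0.40, 0.60, 0.55, 0.45, 0.45, 0.30,
              0.60, 0.60, 0.40, 0.40),
    adist = c(5.05, 4.55, 4.05, 3.40, 2.60, 2.10, 1.70, 1.30, 1.10, 0.40,
              0.35, 0.40, 0.70, 0.35, 0.35, 0.50, 0.45, 0.40, 0.40, 0.25,
              0.50, 0.50, 0.32, 0.32),
    cref  = c(480, 490, 500, 520, 560, 610, 650, 690, 550, 650, 700, 650,
              600, 700, 700, 680, 680, 750, 750, 800, 800, 800, 900,
              900),
    stringsAsFactors = FALSE)

  set.seed(seed)
  if (jitter > 0) {
    base$len <- base$len * exp(rnorm(nrow(base), 0, jitter))
    base$aprox <- base$aprox * exp(rnorm(nrow(base), 0, jitter))
    base$adist <- pmin(base$adist * exp(rnorm(nrow(base), 0, jitter)),
                       0.99 * base$aprox)
  }

  p1 <- vapply(base$cref, .p1_from_wave_speed, numeric(1),
               p0 = p0, rho = rho)

  is_term <- !(seq_len(nrow(base)) %in% base$parent)
  tree <- data.frame(
    id = seq_len(nrow(base)), parent_id = base$parent,
    length_cm = base$len, area_prox_cm2 = base$aprox,
    area_dist_cm2 = base$adist, p0_mmhg = p0, p1_mmhg = p1,
    visc_coeff = 0,
    terminal_r1 = NA_real_, terminal_r2 = NA_real_,
    terminal_ct = NA_real_)

  # terminal Windkessel distribution: flows roughly proportional to the
  # terminal cross-section; proximal resistance matched to the segment's
  # characteristic impedance to limit spurious reflections
  w <- base$adist[is_term]
  w <- w / sum(w)
  tvr_raw <- 1.1                       # mmHg s/mL, scalable later
  r_tot <- tvr_raw / w
  z_char <- rho * base$cref[is_term] / base$adist[is_term] / .MMHG
  r1 <- pmin(z_char, 0.25 * r_tot)
  r2 <- r_tot - r1
  # vessel compliance at 100 mmHg, then terminal compliances to land the
  # aggregate near 1.1 mL/mmHg
  kap <- .kappa(p1, p0, 100)
  c_vessel <- sum(kap * (base$aprox + base$adist) / 2 * base$len)
  ct_tot <- max(0.15, 1.1 - c_vessel)
  tree$terminal_r1[is_term] <- r1
  tree$terminal_r2[is_term] <- r2
  tree$terminal_ct[is_term] <- ct_tot * w

  attr(tree, "names_long") <- base$name
  class(tree) <- c("av_tree", "data.frame")
  if (n_segments == 103) tree <- .subdivide_tree(tree)
  validate_geometry(tree)
  tree
}

# split segments into sub-segments (areas interpolated, terminals kept on
# the last piece) until the tree has exactly 103 segments
.subdivide_tree <- function(tree) {
  k <- rep(4L, nrow(tree))
  extra <- 103L - sum(k)              # 24*4 = 96, 7 more needed
  k[order(tree$length_cm, decreasing = TRUE)[seq_len(extra)]] <- 5L
  new_rows <- list()
  first_piece <- integer(nrow(tree))  # new id of each old segment's head
  last_piece <- integer(nrow(tree))
  nid <- 0L
  for (i in seq_len(nrow(tree))) {
    ki <- k[i]
    a <- seq(tree$area_prox_cm2[i], tree$area_dist_cm2[i], length.out = ki + 1)
    for (j in seq_len(ki)) {
      nid <- nid + 1L
      r <- tree[i, ]
      r$id <- nid
      r$length_cm <- tree$length_cm[i] / ki
      r$area_prox_cm2 <- a[j]
      r$area_dist_cm2 <- a[j + 1]
      if (j < ki) { r$terminal_r1 <- r$terminal_r2 <- r$terminal_ct <- NA_real_ }
      r$parent_id <- if (j == 1) -i else nid - 1L  # placeholder, fixed below
      new_rows[[nid]] <- r
      if (j == 1) first_piece[i] <- nid
      if (j == ki) last_piece[i] <- nid
    }
  }
  out <- do.call(rbind, new_rows)
  for (i in seq_len(nrow(tree))) {
    head_id <- first_piece[i]
    old_parent <- tree$parent_id[i]
    out$parent_id[head_id] <- if (old_parent == 0) 0L else last_piece[old_parent]
  }
  rownames(out) <- NULL
  class(out) <- c("av_tree", "data.frame")
  out
}

#' Validate an arterial-tree geometry
#'
#' Checks column presence, positivity, single-root connectivity and
#' acyclicity, and completeness of the terminal Windkessel fields.
#'
#' @param tree An `av_tree` data.frame.
#' @return The tree, invisibly; stops with a diagnostic on violation.
#' @export
validate_geometry <- function(tree) {
  miss <- setdiff(.GEOM_COLS, names(tree))
  if (length(miss)) stop("geometry is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tree$id)) stop("geometry has duplicated segment ids")
  with(tree, {
    if (any(length_cm <= 0)) stop("segment lengths must be positive")
    if (any(area_prox_cm2 <= 0) || any(area_dist_cm2 <= 0))
      stop("segment areas must be positive")
    if (any(p1_mmhg <= 0)) stop("wall-law width pressure p1 must be positive")
  })
  roots <- tree$id[tree$parent_id == 0]
  if (length(roots) != 1)
    stop("geometry must have exactly one root segment (parent_id 0)")
  if (!all(tree$parent_id %in% c(0, tree$id)))
    stop("parent_id refers to unknown segments")
  # acyclic + connected: walk up from each segment
  idx <- match(tree$parent_id, tree$id)
  for (i in seq_len(nrow(tree))) {
    seen <- integer(0); j <- i
    while (!is.na(idx[j])) {
      if (j %in% seen) stop("geometry contains a cycle at segment id ",
                            tree$id[i])
      seen <- c(seen, j); j <- idx[j]
      if (length(seen) > nrow(tree)) stop("geometry contains a cycle")
    }
  }
  is_term <- !(tree$id %in% tree$parent_id)
  tfields <- c("terminal_r1", "terminal_r2", "terminal_ct")
  for (f in tfields) {
    if (any(is.na(tree[[f]][is_term])))
      stop("terminal segments must provide ", f)
    if (any(tree[[f]][is_term] <= 0)) stop(f, " must be positive")
    if (any(!is.na(tree[[f]][!is_term])))
      stop(f, " must be empty on internal segments")
  }
  invisible(tree)
}

#' Read an arterial-tree geometry from CSV
#'
#' @param path CSV file with the canonical per-segment columns (terminal
#'   fields empty for internal segments); lines starting with `#` are
#'   comments.
#' @return A validated `av_tree` data.frame.
#' @export
read_geometry <- function(path) {
  tree <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  class(tree) <- c("av_tree", "data.frame")
  validate_geometry(tree)
  tree
}

#' Write an arterial-tree geometry to CSV
#'
#' @param tree An `av_tree` data.frame.
#' @param path Output path.
#' @param header_note Optional comment line(s) written before the header.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(tree, path,
                           header_note = "synthetic arterial tree (non-anatomical)") {
  validate_geometry(tree)
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_note) writeLines(paste0("# ", h), con)
  df <- as.data.frame(tree)[, .GEOM_COLS]
  # fixed significant-digit formatting keeps output byte-identical per seed
  for (col in setdiff(.GEOM_COLS, c("id", "parent_id"))) {
    df[[col]] <- ifelse(is.na(df[[col]]), "",
                        sprintf("%.10g", df[[col]]))
  }
  writeLines(paste(.GEOM_COLS, collapse = ","), con)
  writeLines(do.call(paste, c(df, sep = ",")), con)
  invisible(path)
}

#' Packaged default geometry
#'
#' Loads the 24-segment synthetic tree shipped with the package.
#'
#' @return An `av_tree` data.frame.
#' @export
default_tree <- function() {
  read_geometry(system.file("extdata", "tree24.csv", package = "stenosim",
                            mustWork = TRUE))
}

# ---------------------------------------------------------------------------
# discretization: av_tree -> engine geometry list (CGS)
# ---------------------------------------------------------------------------
.discretize <- function(tree, dx_cm = 1, mu = 0.04, gamma_v = 9,
                        rho = 1.06, pref = 100) {
  validate_geometry(tree)
  n <- nrow(tree)
  nn <- pmax(3L, as.integer(round(tree$length_cm / dx_cm)) + 1L)
  off <- c(0L, cumsum(nn))[seq_len(n)]
  dx <- tree$length_cm / (nn - 1)
  Aref <- P0 <- P1 <- Amax <- numeric(sum(nn))
  for (i in seq_len(n)) {
    j <- off[i] + seq_len(nn[i])
    Aref[j] <- seq(tree$area_prox_cm2[i], tree$area_dist_cm2[i],
                   length.out = nn[i])
    P0[j] <- tree$p0_mmhg[i] * .MMHG
    P1[j] <- tree$p1_mmhg[i] * .MMHG
    u <- (pref - tree$p0_mmhg[i]) / tree$p1_mmhg[i]
    Amax[j] <- Aref[j] / (0.5 + atan(u) / pi)
  }
  id2idx <- function(ids) match(ids, tree$id) - 1L  # 0-based
  has_child <- tree$id %in% tree$parent_id
  jn_parent <- id2idx(tree$id[has_child])
  jn_children <- lapply(tree$id[has_child],
                        function(pid) id2idx(tree$id[tree$parent_id == pid]))
  is_term <- !(tree$id %in% tree$parent_id)
  list(nn = nn, off = off, dx = dx,
       visc = tree$visc_coeff * .MMHG,
       Amax = Amax, P0 = P0, P1 = P1, Aref = Aref,
       root_seg = id2idx(tree$id[tree$parent_id == 0]),
       jn_parent = as.integer(jn_parent), jn_children = jn_children,
       term_seg = as.integer(id2idx(tree$id[is_term])),
       term_R1 = tree$terminal_r1[is_term] * .MMHG,
       term_R2 = tree$terminal_r2[is_term] * .MMHG,
       term_Ct = tree$terminal_ct[is_term] / .MMHG,
       mu = mu, rho = rho, gamma_v = gamma_v)
}

# largest stable time step for a discretized tree at a conservative
# high-pressure state, with margin for advective velocity
.auto_dt <- function(g, p_hi_mmhg = 220, u_margin = 350, safety = 0.75) {
  P <- p_hi_mmhg * .MMHG
  dadp <- g$Amax / (pi * g$P1 * (1 + ((P - g$P0) / g$P1)^2))
  A <- g$Amax * (0.5 + atan((P - g$P0) / g$P1) / pi)
  c_hi <- sqrt(A / (g$rho * dadp))
  dx_node <- rep(g$dx, g$nn)
  min(safety * dx_node / (c_hi + u_margin))
}

#' @export
print.av_tree <- function(x, ...) {
  is_term <- !(x$id %in% x$parent_id)
  cat(sprintf("Arterial tree: %d segments (%d terminal), total length %.0f cm\n",
              nrow(x), sum(is_term), sum(x$length_cm)))
  agg <- aggregate_afterload(x)
  cat(sprintf("  aggregate TVR %.3g mmHg s/mL, TAC %.3g mL/mmHg (at 100 mmHg)\n",
              agg$tvr, agg$tac))
  invisible(x)
}
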