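# Swept-tube geometry generators. All three generators (straight duct,
# curved bend, two-channel nasal surrogate) produce watertight triangulated
# tubes by sweeping a (possibly varying) elliptic cross-section along an
# analytic centerline, then capping the two ends with inlet/outlet fans.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# Orthonormal frame for a unit tangent: N1 horizontal (z x T), N2 = T x N1.
frame_from_tangent <- function(T) {
  n1 <- cbind(-T[, 2], T[, 1], 0)
  len <- sqrt(rowSums(n1^2))
  if (any(len < 1e-9)) stop("centerline tangent parallel to z is unsupported")
  n1 <- n1 / len
  n2 <- cbind(T[, 2] * n1[, 3] - T[, 3] * n1[, 2],
              T[, 3] * n1[, 1] - T[, 1] * n1[, 3],
              T[, 1] * n1[, 2] - T[, 2] * n1[, 1])
  list(n1 = n1, n2 = n2)
}

# Build a surface_mesh from a station table. `st` is a data.frame with
# columns s, cx..cz, tx..tz, a, b, region. patch_fun(s, theta, region)
# returns the patch label of each wall quad; rough_fun(s, theta) an optional
# multiplicative radial perturbation.
sweep_mesh <- function(st, n_theta, patch_fun = NULL, rough_fun = NULL,
                       meta = list()) {
  nS <- nrow(st)
  Tm <- as.matrix(st[, c("tx", "ty", "tz")])
  fr <- frame_from_tangent(Tm)
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  ct <- cos(theta); stn <- sin(theta)

  # ring vertices: station-major ordering
  Vx <- outer(st$cx, rep(1, n_theta))
  Vy <- outer(st$cy, rep(1, n_theta))
  Vz <- outer(st$cz, rep(1, n_theta))
  rx <- outer(st$b * fr$n1[, 1], ct) + outer(st$a * fr$n2[, 1], stn)
  ry <- outer(st$b * fr$n1[, 2], ct) + outer(st$a * fr$n2[, 2], stn)
  rz <- outer(st$b * fr$n1[, 3], ct) + outer(st$a * fr$n2[, 3], stn)
  if (!is.null(rough_fun)) {
    fac <- rough_fun(matrix(st$s, nS, n_theta),
                     matrix(theta, nS, n_theta, byrow = TRUE))
    rx <- rx * fac; ry <- ry * fac; rz <- rz * fac
  }
  V <- cbind(as.vector(Vx + rx), as.vector(Vy + ry), as.vector(Vz + rz))
  # vertex index of station i, angular slot j (1-based)
  vid <- function(i, j) (j - 1L) * nS + i

  i <- rep(seq_len(nS - 1L), n_theta)
  j <- rep(seq_len(n_theta), each = nS - 1L)
  jp <- ifelse(j == n_theta, 1L, j + 1L)
  # outward winding: (N1, N2, T) is right-handed, theta runs counterclockwise
  # seen against the sweep direction
  tri1 <- cbind(vid(i, j), vid(i + 1L, jp), vid(i + 1L, j))
  tri2 <- cbind(vid(i, j), vid(i, jp), vid(i + 1L, jp))
  s_mid <- (st$s[i] + st$s[i + 1L]) / 2
  th_mid <- theta[j] + pi / n_theta
  reg_mid <- st$region[i]
  if (is.null(patch_fun)) {
    wall_patch <- reg_mid
  } else {
    wall_patch <- patch_fun(s_mid, th_mid, reg_mid)
  }

  c_in <- nrow(V) + 1L
  c_out <- nrow(V) + 2L
  V <- rbind(V, c(st$cx[1], st$cy[1], st$cz[1]),
             c(st$cx[nS], st$cy[nS], st$cz[nS]))
  jj <- seq_len(n_theta)
  jjp <- c(jj[-1], 1L)
  cap_in <- cbind(rep(c_in, n_theta), vid(1L, jjp), vid(1L, jj))
  cap_out <- cbind(rep(c_out, n_theta), vid(nS, jj), vid(nS, jjp))

  F <- rbind(tri1, tri2, cap_in, cap_out)
  patch <- c(wall_patch, wall_patch,
             rep("inlet", n_theta), rep("outlet", n_theta))

  regions <- unique(c(wall_patch))
  side_of <- function(p) {
    if (grepl("_R$", p)) "R" else if (grepl("_L$", p)) "L" else "central"
  }
  pt <- data.frame(
    patch = c(regions, "inlet", "outlet"),
    role = c(rep("wall", length(regions)), "inlet", "outlet"),
    region = c(regions, "inlet", "outlet"),
    side = c(vapply(regions, side_of, character(1)), "R", "L"),
    stringsAsFactors = FALSE)

  fr_meta <- list(stations = cbind(st, n1x = fr$n1[, 1], n1y = fr$n1[, 2],
                                   n1z = fr$n1[, 3], n2x = fr$n2[, 1],
                                   n2y = fr$n2[, 2], n2z = fr$n2[, 3]))
  sweep <- c(fr_meta, meta)
  sweep$inlet_center <- c(st$cx[1], st$cy[1], st$cz[1])
  sweep$inlet_tangent <- Tm[1, ]
  sweep$inlet_frame <- list(n1 = fr$n1[1, ], n2 = fr$n2[1, ])
  sweep$inlet_ab <- c(st$a[1], st$b[1])
  sweep$stations$b <- st$b  # min channel half-width used by voxelize()

  surface_mesh(V, F, patch, pt, sweep = sweep)
}

#' Straight circular duct
#'
#' Validation geometry: cylinder of given radius and length along +x with
#' `inlet` (x = 0), `outlet` (x = length) and `wall` patches.
#'
#' @param radius,length duct radius and length (m), > 0.
#' @param n_theta circumferential segments (>= 8).
#' @param n_axial axial stations (>= 2).
#' @return a `surface_mesh`.
#' @export
build_duct <- function(radius, length, n_theta = 64L, n_axial = 33L) {
  if (radius <= 0 || length <= 0) stop("parameter error: non-positive duct dimensions")
  if (n_theta < 8L) stop("parameter error: need >= 8 circumferential segments")
  s <- seq(0, length, length.out = n_axial)
  st <- data.frame(s = s, cx = s, cy = 0, cz = 0, tx = 1, ty = 0, tz = 0,
                   a = radius, b = radius, region = "wall",
                   stringsAsFactors = FALSE)
  m <- sweep_mesh(st, n_theta,
                  meta = list(kind = "duct", radius = radius, length = length,
                              axis_point = c(0, 0, 0), axis_dir = c(1, 0, 0)))
  m
}

#' Curved-duct (bend) geometry
#'
#' A circular tube following an entry straight, a circular arc of given bend
#' radius and angle in the x-y plane, and an exit straight. The classic
#' deposition-validation geometry for impaction of particles in curvature.
#'
#' @param tube_radius tube (inner) radius (m).
#' @param bend_radius centerline radius of the curved part (m); must exceed
#'   `tube_radius`.
#' @param angle bend angle in radians, in (0, pi].
#' @param n_theta circumferential segments.
#' @param straight length (m) of the straight extensions (default 4 radii).
#' @param ds target station spacing (m).
#' @return a `surface_mesh`; curved centerline length `bend_radius * angle`
#'   is stored in the sweep metadata.
#' @export
build_bend <- function(tube_radius, bend_radius, angle, n_theta = 48L,
                       straight = 4 * tube_radius, ds = tube_radius / 2) {
  if (tube_radius <= 0) stop("parameter error: non-positive tube radius")
  if (bend_radius <= tube_radius)
    stop("parameter error: bend radius must exceed tube radius")
  if (!(angle > 0 && angle <= pi)) stop("parameter error: angle must be in (0, pi]")

  n1 <- max(2L, ceiling(straight / ds))
  s1 <- seq(0, straight, length.out = n1 + 1L)
  p1 <- cbind(s1, 0, 0)
  t1 <- cbind(1, 0, 0)[rep(1, length(s1)), , drop = FALSE]

  n2 <- max(8L, ceiling(bend_radius * angle / ds))
  phi <- seq(0, angle, length.out = n2 + 1L)[-1]
  ctr <- c(straight, bend_radius, 0)
  p2 <- cbind(ctr[1] + bend_radius * sin(phi), ctr[2] - bend_radius * cos(phi), 0)
  t2 <- cbind(cos(phi), sin(phi), 0)

  tend <- c(cos(angle), sin(angle), 0)
  n3 <- max(2L, ceiling(straight / ds))
  s3 <- seq(0, straight, length.out = n3 + 1L)[-1]
  p3 <- cbind(p2[nrow(p2), 1] + s3 * tend[1], p2[nrow(p2), 2] + s3 * tend[2], 0)
  t3 <- matrix(tend, nrow = length(s3), ncol = 3, byrow = TRUE)

  P <- rbind(p1, p2, p3)
  Tm <- rbind(t1, t2, t3)
  s <- c(s1, straight + bend_radius * phi,
         straight + bend_radius * angle + s3)
  st <- data.frame(s = s, cx = P[, 1], cy = P[, 2], cz = P[, 3],
                   tx = Tm[, 1], ty = Tm[, 2], tz = Tm[, 3],
                   a = tube_radius, b = tube_radius, region = "wall",
                   stringsAsFactors = FALSE)
  sweep_mesh(st, n_theta,
             meta = list(kind = "bend", radius = tube_radius,
                         bend_radius = bend_radius, angle = angle,
                         arc_length = bend_radius * angle))
}

#' Default parameters of the synthetic nasal surrogate
#'
#' The surrogate preserves the topology of a closed-soft-palate bi-directional
#' nasal path: a 45-degree inlet nosepiece, a right channel with a valve
#' constriction, a 180-degree U-bend (nasopharynx), a left channel, and a
#' 45-degree outlet nosepiece. Channels are tall elliptic slits (half-height
#' `a`, half-width `b`), which reproduces the large epithelial
#' surface-to-volume ratio of real nasal passages; dorsal wall bands near the
#' posterior end of each channel are labelled as olfactory patches. Default
#' lengths are calibrated so the olfactory patch areas are about 330 mm^2
#' (right) and 337 mm^2 (left) and the total-wall to olfactory area ratio is
#' about 64, matching the reported anatomy.
#'
#' @param ... overrides of the default parameters.
#' @return named list of geometry parameters (all lengths in metres, angles
#'   in radians).
#' @export
nasal_params <- function(...) {
  p <- list(
    channel_half_height = 0.030,  # a: dorsoventral slit half-height
    channel_half_width = 0.002,   # b: left-right slit half-width
    channel_length = 0.1422,
    ubend_radius = 0.020,
    nosepiece_radius = 0.005,
    nosepiece_length = 0.025,
    nosepiece_angle = 45 * pi / 180,
    fillet_radius = 0.010,
    vestibule_length = 0.015,     # morph zone circle -> slit
    valve_ratio = 0.8,            # height constriction factor at the valve
    valve_length = 0.010,
    valve_offset = 0.008,         # valve start after the vestibule morph
    olf_theta_halfwidth = 1.0,    # dorsal angular half-band (rad)
    olf_len_R = 0.012174,         # streamwise extent of the olfactory bands
    olf_len_L = 0.012457,
    olf_end_offset = 0.006,       # distance from the posterior channel end
    roughness_amp = 0.01,
    roughness_lambda = 0.012,
    n_theta = 64L,
    ds_channel = 0.0012,
    ds_arc = 0.0018)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stop("unknown nasal parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  p
}

#' Synthetic bi-directional nasal surrogate geometry
#'
#' Generates the watertight two-channel U-bend surrogate described in
#' [nasal_params()], with wall patches `vestibule_R/L`, `valve_R/L`,
#' `turbinate_R/L`, `olfactory_R/L` and `nasopharynx`, plus one `inlet` and
#' one `outlet` cap on the two nosepieces. A small seeded sinusoidal wall
#' roughness emulates mucosal irregularity; identical `(params, seed)` give
#' identical meshes.
#'
#' @param params parameter list from [nasal_params()].
#' @param seed integer seed for the wall-roughness phases.
#' @return a `surface_mesh` with sweep metadata (stations, olfactory windows).
#' @export
build_nasal_surrogate <- function(params = nasal_params(), seed = 1L) {
  p <- params
  if (!(p$valve_ratio > 0 && p$valve_ratio < 1))
    stop("parameter error: valve constriction ratio must be in (0,1)")
  if (p$olf_len_R + p$olf_end_offset > p$channel_length - p$vestibule_length ||
      p$olf_len_L + p$olf_end_offset > p$channel_length - p$vestibule_length)
    stop("parameter error: olfactory pocket larger than channel")
  if (p$fillet_radius <= p$nosepiece_radius)
    stop("parameter error: fillet radius must exceed nosepiece radius")

  alpha <- p$nosepiece_angle
  rf <- p$fillet_radius
  Ln <- p$nosepiece_length
  Lch <- p$channel_length
  Ru <- p$ubend_radius

  # --- centerline pieces (right side: entry) -------------------------------
  # nosepiece: descending at alpha toward +y; channel axis at z = 0.
  dir_in <- c(0, cos(alpha), -sin(alpha))
  arc_drop <- rf * (1 - cos(alpha))
  # place the channel start at the origin; work backwards for the inlet.
  ch0_R <- c(0, 0, 0)
  arc_ctr_R <- ch0_R + c(0, -rf * sin(alpha) * 0, 0) # filled below
  # fillet: direction angle th from +y in the y-z plane goes -alpha -> 0
  # center of curvature is above the arc (at +z side).
  # arc end (joins channel) at angle 0: pos = ctr + rf*(0, sin(0), -cos(0))
  arc_ctr_R <- ch0_R - c(0, 0, -rf)      # ctr = end - rf*(0,0,-1)
  arc_pt <- function(ctr, th) ctr + rf * c(0, sin(th), -cos(th))
  arc_start_R <- arc_pt(arc_ctr_R, -alpha)
  inlet_pt <- arc_start_R - Ln * dir_in

  pieces <- list()
  add_piece <- function(pieces, fun, len, ds, region)
    c(pieces, list(list(fun = fun, len = len, ds = ds, region = region)))

  pieces <- add_piece(pieces, function(l)
    list(c = t(vapply(l, function(li) inlet_pt + li * dir_in, numeric(3))),
         t = matrix(dir_in, length(l), 3, byrow = TRUE)),
    Ln, p$ds_arc, "vestibule_R")

  pieces <- add_piece(pieces, function(l) {
    th <- -alpha + l / rf
    list(c = t(vapply(th, function(ti) arc_pt(arc_ctr_R, ti), numeric(3))),
         t = cbind(0, cos(th), sin(th)))
  }, rf * alpha, p$ds_arc, "vestibule_R")

  # olfactory windows in channel-local arclength (filled into global s later);
  # stations are inserted exactly at the window edges so the olfactory patch
  # area varies continuously with the window length.
  olf_loc_R <- Lch - p$olf_end_offset - c(p$olf_len_R, 0)
  olf_loc_L <- p$olf_end_offset + c(0, p$olf_len_L)
  pieces <- add_piece(pieces, function(l)
    list(c = cbind(0, l, 0), t = matrix(c(0, 1, 0), length(l), 3, byrow = TRUE)),
    Lch, p$ds_channel, "channel_R")
  pieces[[length(pieces)]]$extra <- olf_loc_R

  ub_ctr <- c(Ru, Lch, 0)
  pieces <- add_piece(pieces, function(l) {
    phi <- l / Ru
    list(c = cbind(ub_ctr[1] - Ru * cos(phi), ub_ctr[2] + Ru * sin(phi), 0),
         t = cbind(sin(phi), cos(phi), 0))
  }, Ru * pi, p$ds_arc, "nasopharynx")

  chL_x <- 2 * Ru
  pieces <- add_piece(pieces, function(l)
    list(c = cbind(chL_x, Lch - l, 0),
         t = matrix(c(0, -1, 0), length(l), 3, byrow = TRUE)),
    Lch, p$ds_channel, "channel_L")
  pieces[[length(pieces)]]$extra <- olf_loc_L

  dir_out <- c(0, -cos(alpha), sin(alpha))
  arc_ctr_L <- c(chL_x, 0, rf)
  arc_pt_L <- function(th) arc_ctr_L + rf * c(0, -sin(th), -cos(th))
  pieces <- add_piece(pieces, function(l) {
    th <- l / rf
    list(c = t(vapply(th, arc_pt_L, numeric(3))),
         t = cbind(0, -cos(th), sin(th)))
  }, rf * alpha, p$ds_arc, "vestibule_L")

  outlet_start <- arc_pt_L(alpha)
  pieces <- add_piece(pieces, function(l)
    list(c = t(vapply(l, function(li) outlet_start + li * dir_out, numeric(3))),
         t = matrix(dir_out, length(l), 3, byrow = TRUE)),
    Ln, p$ds_arc, "vestibule_L")

  # --- sample stations ------------------------------------------------------
  st_list <- list()
  s0 <- 0
  piece_s0 <- numeric(length(pieces))
  for (q in seq_along(pieces)) {
    pc <- pieces[[q]]
    piece_s0[q] <- s0
    nq <- max(2L, ceiling(pc$len / pc$ds))
    l <- seq(0, pc$len, length.out = nq + 1L)
    if (!is.null(pc$extra)) {
      l <- sort(unique(c(l, pc$extra)))
      l <- l[c(TRUE, diff(l) > 1e-9)]
    }
    if (q > 1L) l <- l[-1]
    ct <- pc$fun(l)
    st_list[[q]] <- data.frame(s = s0 + l, cx = ct$c[, 1], cy = ct$c[, 2],
                               cz = ct$c[, 3], tx = ct$t[, 1], ty = ct$t[, 2],
                               tz = ct$t[, 3], region = pc$region,
                               stringsAsFactors = FALSE)
    s0 <- s0 + pc$len
  }
  st <- do.call(rbind, st_list)
  s_total <- s0

  # --- cross-section law ----------------------------------------------------
  a_ch <- p$channel_half_height
  b_ch <- p$channel_half_width
  rn <- p$nosepiece_radius
  s_ch0_R <- piece_s0[3]                 # start of right channel
  s_ch1_R <- piece_s0[4]                 # end of right channel / bend start
  s_ch0_L <- piece_s0[5]                 # start of left channel (at bend exit)
  s_ch1_L <- piece_s0[6]                 # end of left channel
  Lv <- p$vestibule_length

  morph_R <- smoothstep((st$s - s_ch0_R) / Lv)          # 0 circle -> 1 slit
  morph_L <- smoothstep((s_ch1_L - st$s) / Lv)
  morph <- pmin(morph_R, morph_L)
  a <- rn + (a_ch - rn) * morph
  b <- rn + (b_ch - rn) * morph

  valve_bump <- function(s, s_start) {
    x <- (s - s_start) / p$valve_length
    ifelse(x > 0 & x < 1, sin(pi * x)^2, 0)
  }
  sv_R <- s_ch0_R + Lv + p$valve_offset
  sv_L <- s_ch1_L - Lv - p$valve_offset - p$valve_length
  vb <- valve_bump(st$s, sv_R) + valve_bump(st$s, sv_L)
  a <- a * (1 - (1 - p$valve_ratio) * vb)

  st$a <- a
  st$b <- b

  # region relabelling along s
  reg <- st$region
  in_R <- reg == "channel_R"
  in_L <- reg == "channel_L"
  reg[in_R] <- ifelse(st$s[in_R] < s_ch0_R + Lv, "vestibule_R",
                 ifelse(st$s[in_R] >= sv_R & st$s[in_R] < sv_R + p$valve_length,
                        "valve_R", "turbinate_R"))
  reg[in_L] <- ifelse(st$s[in_L] > s_ch1_L - Lv, "vestibule_L",
                 ifelse(st$s[in_L] >= sv_L & st$s[in_L] < sv_L + p$valve_length,
                        "valve_L", "turbinate_L"))
  st$region <- reg

  # olfactory windows: dorsal bands ending olf_end_offset before the bend
  olf_R <- c(s_ch1_R - p$olf_end_offset - p$olf_len_R,
             s_ch1_R - p$olf_end_offset)
  olf_L <- c(s_ch0_L + p$olf_end_offset,
             s_ch0_L + p$olf_end_offset + p$olf_len_L)
  thw <- p$olf_theta_halfwidth
  patch_fun <- function(s, theta, region) {
    dth <- abs(theta - pi / 2)
    out <- region
    out[region == "turbinate_R" & s >= olf_R[1] & s < olf_R[2] & dth < thw] <-
      "olfactory_R"
    out[region == "turbinate_L" & s >= olf_L[1] & s < olf_L[2] & dth < thw] <-
      "olfactory_L"
    out
  }

  ph <- with_seed(seed, runif(4, 0, 2 * pi))
  amp <- p$roughness_amp
  lam <- p$roughness_lambda
  rough_fun <- function(s, theta) {
    w <- smoothstep((s - (s_ch0_R + Lv)) / Lv) *
      smoothstep(((s_ch1_L - Lv) - s) / Lv)
    1 + amp * w * (sin(2 * pi * s / lam + ph[1]) * cos(3 * theta + ph[2]) +
                   0.6 * sin(2 * pi * s / (1.7 * lam) + ph[3]) *
                     cos(5 * theta + ph[4]))
  }
  if (amp == 0) rough_fun <- NULL

  m <- sweep_mesh(st, p$n_theta, patch_fun = patch_fun, rough_fun = rough_fun,
                  meta = list(kind = "nasal_surrogate", params = p, seed = seed,
                              s_total = s_total, olf_window_R = olf_R,
                              olf_window_L = olf_L,
                              bend_window = c(s_ch1_R, s_ch0_L)))
  # surrogate-specific side tags for the central patches
  pt <- m$patch_table
  pt$side[pt$patch == "nasopharynx"] <- "central"
  m$patch_table <- pt
  m
}

#' Olfactory / cavity area summary of a surrogate
#' @param mesh a nasal surrogate `surface_mesh`.
#' @return list with olfactory areas (mm^2) and the wall-to-olfactory ratio.
#' @export
surrogate_area_summary <- function(mesh) {
  pa <- patch_areas(mesh) * 1e6  # mm^2
  roles <- mesh$patch_table$role[match(names(pa), mesh$patch_table$patch)]
  wall <- sum(pa[roles == "wall"])
  olf_R <- unname(pa["olfactory_R"])
  olf_L <- unname(pa["olfactory_L"])
  list(olfactory_R_mm2 = olf_R, olfactory_L_mm2 = olf_L,
       wall_total_mm2 = wall,
       cavity_olfactory_ratio = wall / (olf_R + olf_L))
}
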