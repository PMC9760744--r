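# Articulated pedestrian model: 11 rigid ellipsoid segments on a kinematic
# tree, scaled from a reference proportion table.

# Reference proportions at stature 1.75 m. Stack fractions (z_lo, z_hi) sum
# to 1.0 along the leg-pelvis-torso-neck-head chain; limb segments hang off
# the chain. Mass fractions sum exactly to 1. Widths (a = fore-aft, b =
# lateral semi-axes, metres at 1.75 m stature) scale linearly with stature.
.ped_reference <- function() {
  seg <- data.frame(
    name  = c("pelvis", "mid_torso", "upper_torso", "neck", "head",
              "thigh_r", "thigh_l", "leg_r", "leg_l", "arm_r", "arm_l"),
    mfrac = c(0.145, 0.160, 0.170, 0.015, 0.070,
              0.100, 0.100, 0.070, 0.070, 0.050, 0.050),
    z_lo  = c(0.530, 0.605, 0.710, 0.820, 0.872,
              0.285, 0.285, 0.000, 0.000, NA, NA),
    z_hi  = c(0.605, 0.710, 0.820, 0.872, 1.000,
              0.530, 0.530, 0.285, 0.285, NA, NA),
    a     = c(0.100, 0.100, 0.110, 0.050, 0.080,
              0.075, 0.075, 0.055, 0.055, 0.050, 0.050),
    b     = c(0.160, 0.140, 0.170, 0.050, 0.075,
              0.075, 0.075, 0.055, 0.055, 0.050, 0.050),
    y_off = c(0, 0, 0, 0, 0, -0.090, 0.090, -0.090, 0.090, -0.205, 0.205),
    stringsAsFactors = FALSE
  )
  # merged bent arm (hands in pockets): 0.30 m long at 1.75 m stature,
  # hanging from the shoulder (z 0.820) slightly forward of the torso line
  arm_len <- 0.300 / 1.75
  seg$z_hi[seg$name %in% c("arm_r", "arm_l")] <- 0.820
  seg$z_lo[seg$name %in% c("arm_r", "arm_l")] <- 0.820 - arm_len
  seg
}

.ped_joints_spec <- function() {
  # joint attachment heights are stack fractions; krot N*m/rad, crot
  # N*m*s/rad, stop = range of motion about neutral standing, rad
  data.frame(
    name   = c("waist", "chest", "neck_base", "head_neck",
               "shoulder_r", "shoulder_l", "hip_r", "hip_l",
               "knee_r", "knee_l"),
    parent = c("pelvis", "mid_torso", "upper_torso", "neck",
               "upper_torso", "upper_torso", "pelvis", "pelvis",
               "thigh_r", "thigh_l"),
    child  = c("mid_torso", "upper_torso", "neck", "head",
               "arm_r", "arm_l", "thigh_r", "thigh_l",
               "leg_r", "leg_l"),
    z_j    = c(0.605, 0.710, 0.820, 0.872,
               0.820, 0.820, 0.530, 0.530, 0.285, 0.285),
    y_j    = c(0, 0, 0, 0, -0.180, 0.180, -0.090, 0.090, -0.090, 0.090),
    krot   = c(250, 250, 60, 40, 40, 40, 150, 150, 80, 80),
    crot   = c(15, 15, 3, 3, 3, 3, 10, 10, 6, 6),
    stop   = c(0.6, 0.6, 0.9, 0.9, 1.5, 1.5, 1.8, 1.8, 2.0, 2.0),
    stringsAsFactors = FALSE
  )
}

#' Posture presets
#'
#' Named joint-angle tables (radians). Flexion angles rotate about the local
#' left-pointing y axis: positive = limb swings forward. The
#' `"walking_arms_in_pockets"` preset puts the right leg in front, the left
#' leg behind in a walking gait, arms bent with hands in pockets, and the
#' body leaning slightly to the left.
#'
#' @param name preset name (`"walking_arms_in_pockets"` or `"standing"`)
#' @return named numeric vector of joint angles in radians
#' @export
posture_preset <- function(name = "walking_arms_in_pockets") {
  presets <- list(
    standing = c(waist_flexion = 0),
    walking_arms_in_pockets = c(
      hip_r_flexion = 0.35, hip_l_flexion = -0.25,
      knee_r_flexion = -0.08, knee_l_flexion = -0.50,
      shoulder_r_flexion = 0.20, shoulder_l_flexion = 0.20,
      waist_roll = 0.08, waist_flexion = 0.05,
      head_flexion = 0, head_yaw = 0
    )
  )
  if (!name %in% names(presets)) {
    stop("unknown posture preset '", name, "'; known: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[name]]
}

# map a named posture table to per-joint rotations (axis-angle list)
.posture_to_joint_rot <- function(posture) {
  rot <- list()
  get0n <- function(key) if (key %in% names(posture)) posture[[key]] else 0
  rot$waist <- .quat_from_euler(get0n("waist_flexion"), get0n("waist_roll"), 0)
  rot$chest <- .quat_from_euler(0, 0, 0)
  rot$neck_base <- .quat_from_euler(0, 0, 0)
  rot$head_neck <- .quat_from_euler(get0n("head_flexion"), 0, get0n("head_yaw"))
  rot$shoulder_r <- .quat_from_euler(get0n("shoulder_r_flexion"), 0, 0)
  rot$shoulder_l <- .quat_from_euler(get0n("shoulder_l_flexion"), 0, 0)
  rot$hip_r <- .quat_from_euler(get0n("hip_r_flexion"), 0, 0)
  rot$hip_l <- .quat_from_euler(get0n("hip_l_flexion"), 0, 0)
  rot$knee_r <- .quat_from_euler(get0n("knee_r_flexion"), 0, 0)
  rot$knee_l <- .quat_from_euler(get0n("knee_l_flexion"), 0, 0)
  rot
}

# quaternion helpers (w, x, y, z), local frame: x forward, y left, z up
.quat_from_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}
# flexion pitch about -y so positive angle swings the limb forward (+x);
# roll about x (positive tips left); yaw about z; applied yaw*roll*pitch
.quat_from_euler <- function(pitch, roll, yaw) {
  .quat_mul(.quat_from_axis(c(0, 0, 1), yaw),
            .quat_mul(.quat_from_axis(c(1, 0, 0), roll),
                      .quat_from_axis(c(0, -1, 0), pitch)))
}
.quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}
.quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])
.quat_rot <- function(q, v) {
  u <- q[2:4]
  v + 2 * .cross3(u, .cross3(u, v) + q[1] * v)
}
.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
.quat_angle <- function(q) 2 * atan2(sqrt(sum(q[2:4]^2)), abs(q[1]))

#' Build a scaled articulated pedestrian model
#'
#' Eleven rigid ellipsoid segments (head, neck, upper/mid torso, pelvis,
#' merged left/right arms, left/right thighs, left/right legs+feet) on a
#' kinematic tree. Segment lengths scale linearly with stature and masses
#' with body mass from a fixed reference proportion table. Marker attachment
#' points are placed at the right shoulder, the middle of the right thigh
#' (outer face), the outer middle of the right calf, and the head vertex.
#'
#' @param height stature in metres, within [1.0, 2.2]
#' @param mass body mass in kg, within [30, 150]
#' @param posture preset name or named joint-angle vector (radians)
#' @return an object of class `pedestrian_model`
#' @export
build_pedestrian <- function(height = 1.75, mass = 75,
                             posture = "walking_arms_in_pockets") {
  if (!is.numeric(height) || height < 1.0 || height > 2.2) {
    stop("height must be within [1.0, 2.2] m, got ", height)
  }
  if (!is.numeric(mass) || mass < 30 || mass > 150) {
    stop("mass must be within [30, 150] kg, got ", mass)
  }
  if (is.character(posture)) posture <- posture_preset(posture)

  ref <- .ped_reference()
  js <- .ped_joints_spec()
  s <- height / 1.75  # lateral scale follows stature

  seg <- ref
  seg$mass <- mass * seg$mfrac / sum(seg$mfrac)
  seg$length <- (seg$z_hi - seg$z_lo) * height
  seg$a <- seg$a * s
  seg$b <- seg$b * s
  seg$cz <- seg$length / 2          # long semi-axis
  seg$y0 <- seg$y_off * s
  seg$z0 <- (seg$z_lo + seg$z_hi) / 2 * height

  # arms sit slightly forward of the torso line (hands in pockets)
  seg$x0 <- ifelse(seg$name %in% c("arm_r", "arm_l"), 0.06 * s, 0)

  # solid ellipsoid inertia about principal axes
  seg$Ix <- seg$mass / 5 * (seg$b^2 + seg$cz^2)
  seg$Iy <- seg$mass / 5 * (seg$a^2 + seg$cz^2)
  seg$Iz <- seg$mass / 5 * (seg$a^2 + seg$b^2)

  # validate posture against joint stops
  jrot <- .posture_to_joint_rot(posture)
  for (j in seq_len(nrow(js))) {
    ang <- .quat_angle(jrot[[js$name[j]]])
    if (ang > js$stop[j] + 1e-9) {
      stop("posture angle ", round(ang, 3), " rad exceeds range of motion ",
           js$stop[j], " rad at joint '", js$name[j], "'")
    }
  }

  joints <- js
  joints$z_j <- joints$z_j * height
  joints$y_j <- joints$y_j * s

  markers <- list(
    shoulder_r  = list(segment = "upper_torso",
                       offset = c(0, -0.180 * s, 0.055 * height)),
    thigh_mid_r = list(segment = "thigh_r", offset = c(0, -0.075 * s, 0)),
    calf_mid_r  = list(segment = "leg_r",  offset = c(0, -0.055 * s, 0)),
    head_vertex = list(segment = "head",
                       offset = c(0, 0, 0.064 * height))
  )

  model <- structure(list(
    segments = seg, joints = joints, posture = posture, markers = markers,
    total_height = height, total_mass = mass
  ), class = "pedestrian_model")
  model
}

# Forward kinematics: pose the model with its posture, an overall yaw about
# z, and a base translation; returns world-frame centres and quaternions.
# extra_head (quaternion) composes the design head angles onto the neck-head
# joint.
.pose_pedestrian <- function(model, yaw = 0, base = c(0, 0, 0),
                             extra_head = c(1, 0, 0, 0)) {
  seg <- model$segments
  js <- model$joints
  n <- nrow(seg)
  idx <- setNames(seq_len(n), seg$name)
  jrot <- .posture_to_joint_rot(model$posture)
  jrot$head_neck <- .quat_mul(jrot$head_neck, extra_head)

  qyaw <- .quat_from_axis(c(0, 0, 1), yaw)
  pos <- matrix(0, n, 3)
  quat <- matrix(0, n, 4)
  qrel0 <- matrix(0, max(nrow(js), 0), 4)

  ref_center <- cbind(seg$x0, seg$y0, seg$z0)
  # root = the segment that is nobody's child
  root <- idx[[setdiff(seg$name, js$child)[1]]]
  quat[root, ] <- qyaw
  pos[root, ] <- base + .quat_rot(qyaw, ref_center[root, ])

  # children in spec order (parents precede children)
  for (j in seq_len(nrow(js))) {
    p <- idx[[js$parent[j]]]
    c_ <- idx[[js$child[j]]]
    jref <- c(0, js$y_j[j], js$z_j[j])
    anchor_p <- jref - ref_center[p, ]
    anchor_c <- jref - ref_center[c_, ]
    qj <- jrot[[js$name[j]]]
    quat[c_, ] <- .quat_mul(quat[p, ], qj)
    jw <- pos[p, ] + .quat_rot(quat[p, ], anchor_p)
    pos[c_, ] <- jw - .quat_rot(quat[c_, ], anchor_c)
    qrel0[j, ] <- qj
  }

  anchors_p <- matrix(0, nrow(js), 3)
  anchors_c <- matrix(0, nrow(js), 3)
  for (j in seq_len(nrow(js))) {
    p <- idx[[js$parent[j]]]
    c_ <- idx[[js$child[j]]]
    jref <- c(0, js$y_j[j], js$z_j[j])
    anchors_p[j, ] <- jref - ref_center[p, ]
    anchors_c[j, ] <- jref - ref_center[c_, ]
  }

  list(pos = pos, quat = quat, qrel0 = qrel0,
       anchor_parent = anchors_p, anchor_child = anchors_c,
       parent = unname(idx[js$parent]), child = unname(idx[js$child]))
}

# single free segment, used for drop tests and integrator checks
.single_segment_model <- function(mass = 5, semi = c(0.1, 0.1, 0.1),
                                  center_z = 1) {
  seg <- data.frame(
    name = "body", mfrac = 1, z_lo = NA, z_hi = NA,
    a = semi[1], b = semi[2], y_off = 0, mass = mass,
    length = 2 * semi[3], cz = semi[3], y0 = 0, z0 = center_z, x0 = 0,
    Ix = mass / 5 * (semi[2]^2 + semi[3]^2),
    Iy = mass / 5 * (semi[1]^2 + semi[3]^2),
    Iz = mass / 5 * (semi[1]^2 + semi[2]^2),
    stringsAsFactors = FALSE
  )
  structure(list(
    segments = seg,
    joints = .ped_joints_spec()[0, ],
    posture = c(waist_flexion = 0),
    markers = list(head_vertex = list(segment = "body", offset = c(0, 0, semi[3]))),
    total_height = NA_real_, total_mass = mass
  ), class = "pedestrian_model")
}

#' @export
print.pedestrian_model <- function(x, ...) {
  cat("<pedestrian_model> ", nrow(x$segments), " segments, stature ",
      x$total_height, " m, mass ", x$total_mass, " kg\n", sep = "")
  invisible(x)
}
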