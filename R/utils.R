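# run code under a fixed RNG seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_pa <- function(..., class = "poseangle_error") {
  rlang::abort(paste0(...), class = class)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_pa(sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# coordinate column names for a set of joints, in x/y/z triples
coord_cols <- function(joints) {
  as.vector(t(outer(joints, c("x", "y", "z"), paste, sep = "_")))
}

# extract an n x 3k coordinate matrix (columns joint_x, joint_y, joint_z)
traj_matrix <- function(traj, joints = canonical_joints()) {
  cols <- coord_cols(joints)
  missing <- setdiff(cols, names(traj))
  if (length(missing) > 0) {
    stop_pa("trajectory is missing coordinate columns: ",
            paste(missing, collapse = ", "))
  }
  as.matrix(traj[cols])
}

# one frame of a trajectory as a k x 3 matrix with joint rownames
frame_matrix <- function(traj, frame_row, joints = canonical_joints()) {
  m <- traj_matrix(traj[frame_row, , drop = FALSE], joints)
  matrix(m, ncol = 3, byrow = TRUE,
         dimnames = list(joints, c("x", "y", "z")))
}

# inverse of frame_matrix for a whole series: k x 3 matrix -> named row
flatten_frame <- function(m) {
  v <- as.vector(t(m))
  names(v) <- coord_cols(rownames(m))
  v
}
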