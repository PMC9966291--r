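# internal helpers: error conditions, seeding, small geometry utilities

.stopInvalid <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("fidreg_invalid_input", "fidreg_error")))
}

.stopDegenerate <- function(msg, rank = NA_integer_, iteration = NA_integer_) {
  stop(errorCondition(msg,
    rank = rank, iteration = iteration,
    class = c("fidreg_degenerate_geometry", "fidreg_error")))
}

.stopEmptySelection <- function(msg) {
  stop(errorCondition(msg,
    class = c("fidreg_empty_selection", "fidreg_error")))
}

.stopInvalidRoi <- function(msg) {
  stop(errorCondition(msg, class = c("fidreg_invalid_roi", "fidreg_error")))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed per (stream, replicate, role); keeps every derived
# seed strictly below 2^31 so it is a valid R integer seed.
.subSeed <- function(master, replicate = 0L, role = 0L) {
  m <- as.double(master) %% 1048576          # 2^20
  as.integer((m * 1021 + as.double(replicate) * 131 + as.double(role) * 7 + 1) %%
             2147483629)
}

# total area of a triangulation (used by TriangleMesh validity)
.meshArea <- function(V, F) sum(.triAreas(V, F))

.triAreas <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# per-face unit normals (right-hand winding)
.triNormals <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / sqrt(rowSums(n^2))
}

.asPointMatrix <- function(x, arg = "points") {
  if (is(x, "PointCloud")) return(x@points)
  if (is.matrix(x) && ncol(x) == 3) return(x)
  .stopInvalid(sprintf("%s must be a PointCloud or an n x 3 matrix", arg))
}
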