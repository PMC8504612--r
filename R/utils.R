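`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so seeded draws inside the
#' package never perturb the user's random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# index a 3D/4D array along one axis, keeping dims
axis_slice <- function(a, axis, i) {
  ix <- rep(list(quote(expr = )), length(dim(a)))
  ix[[axis]] <- i
  do.call(`[`, c(list(a), ix, list(drop = FALSE)))
}

axis_assign <- function(a, axis, i, value) {
  ix <- rep(list(quote(expr = )), length(dim(a)))
  ix[[axis]] <- i
  do.call(`[<-`, c(list(a), ix, list(value = value)))
}

#' Forward finite difference along one axis (backward at the last index)
#' @keywords internal
fdiff <- function(a, axis) {
  n <- dim(a)[axis]
  d <- axis_slice(a, axis, 2:n) - axis_slice(a, axis, 1:(n - 1))
  out <- array(0, dim(a))
  out <- axis_assign(out, axis, 1:(n - 1), d)
  axis_assign(out, axis, n, axis_slice(d, axis, n - 1))
}

# adjoint (transpose) of fdiff, needed by the penalty gradients
fdiff_adj <- function(g, axis) {
  n <- dim(g)[axis]
  out <- array(0, dim(g))
  gi <- axis_slice(g, axis, 1:(n - 1))
  out <- axis_assign(out, axis, 1:(n - 1), -gi)
  out <- axis_assign(out, axis, 2:n, axis_slice(out, axis, 2:n) + gi)
  gn <- axis_slice(g, axis, n)
  out <- axis_assign(out, axis, n - 1, axis_slice(out, axis, n - 1) - gn)
  axis_assign(out, axis, n, axis_slice(out, axis, n) + gn)
}

# concatenate 4D tensors along the channel (4th) axis
cat4 <- function(...) {
  xs <- list(...)
  sp <- dim(xs[[1]])[1:3]
  ch <- vapply(xs, function(x) dim(x)[4], integer(1))
  out <- array(0, c(sp, sum(ch)))
  at <- 0L
  for (x in xs) {
    out[, , , at + seq_len(dim(x)[4])] <- x
    at <- at + dim(x)[4]
  }
  out
}

split4 <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(s) {
    out <- x[, , , at + seq_len(s), drop = FALSE]
    at <<- at + s
    out
  })
}

# grid of all 0-based voxel coordinates of a shape, x fastest (column-major)
voxel_grid <- function(shape) {
  as.matrix(expand.grid(
    x = seq_len(shape[1]) - 1,
    y = seq_len(shape[2]) - 1,
    z = seq_len(shape[3]) - 1
  ))
}

# number of voxels in the truncated box window around each voxel
box_count3 <- function(shape, radius) {
  cnt <- lapply(shape, function(n) {
    i <- seq_len(n) - 1
    pmin(i + radius, n - 1) - pmax(i - radius, 0) + 1
  })
  outer(outer(cnt[[1]], cnt[[2]]), cnt[[3]])
}

#' Write a JSON run record for a pipeline invocation
#' @keywords internal
write_run_record <- function(dir, subcommand, config) {
  rec <- list(
    subcommand = subcommand,
    config = config,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("lungwarp")),
    r_version = R.version.string
  )
  path <- file.path(dir, paste0("run_", subcommand, ".json"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
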