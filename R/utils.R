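`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## md5 of an R object via its serialization (provenance bookkeeping)
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

## voxel-centre world coordinates (mm) along each axis of a GridSpec
axisCoords <- function(grid) {
  lapply(1:3, function(i)
    grid@origin[i] + (seq_len(grid@shape[i]) - 1) * grid@voxelSize[i])
}

stopifnot_same_dim <- function(...) {
  args <- list(...)
  d0 <- dim(args[[1]])
  for (a in args[-1])
    if (!identical(dim(a), d0))
      stop("projection stacks have mismatched shapes", call. = FALSE)
  invisible(TRUE)
}
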