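#' Define a bounded continuous design space
#'
#' A design space is an ordered set of named, bounded continuous design
#' variables — strut widths, strut thickness, chamfer radius or balloon
#' length, all in mm for stent problems (any consistent unit works).
#'
#' @param ... Named arguments, each a numeric vector `c(lower, upper)`,
#'   one per design variable; or a single unnamed `data.frame`/list with
#'   columns/fields `name`, `lower`, `upper`.
#'
#' @return An object of class `"design_space"`: a list with `names`
#'   (character), `lower`, `upper` (numeric) and `dim`.
#'
#' @examples
#' # strut widths and thickness of a diamond-shaped stent, mm
#' design_space(w1 = c(0.22, 0.34), w2 = c(0.2, 0.3), t1 = c(0.1, 0.14))
#' # dilatation balloon length, mm
#' design_space(L = c(4.6, 5.1))
#' @export
design_space <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) &&
      (is.data.frame(args[[1L]]) || (is.list(args[[1L]]) && !is.numeric(args[[1L]])))) {
    df <- as.data.frame(args[[1L]], stringsAsFactors = FALSE)
    stopifnot(all(c("name", "lower", "upper") %in% names(df)))
    nm <- as.character(df$name); lo <- as.numeric(df$lower); hi <- as.numeric(df$upper)
  } else {
    if (length(args) < 1L) stop("a design space needs at least one variable")
    nm <- names(args)
    if (is.null(nm) || any(nm == ""))
      stop("every design variable must be named, e.g. design_space(w1 = c(0.22, 0.34))")
    bad <- !vapply(args, function(b) is.numeric(b) && length(b) == 2L && all(is.finite(b)), TRUE)
    if (any(bad))
      stop("bounds must be finite numeric c(lower, upper); offending variable(s): ",
           paste(nm[bad], collapse = ", "))
    lo <- vapply(args, `[`, 0, 1L)
    hi <- vapply(args, `[`, 0, 2L)
  }
  if (length(nm) < 1L) stop("a design space needs at least one variable")
  if (anyDuplicated(nm))
    stop("duplicate variable name(s): ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  swapped <- lo >= hi
  if (any(swapped))
    stop("lower bound must be strictly below upper bound for: ",
         paste(nm[swapped], collapse = ", "))
  structure(list(names = nm, lower = unname(lo), upper = unname(hi),
                 dim = length(nm)),
            class = "design_space")
}

#' @export
print.design_space <- function(x, ...) {
  cat(sprintf("Design space (%d variable%s):\n", x$dim, if (x$dim > 1L) "s" else ""))
  for (i in seq_len(x$dim))
    cat(sprintf("  %-8s [%g, %g]\n", x$names[i], x$lower[i], x$upper[i]))
  invisible(x)
}

#' @export
format.design_space <- function(x, ...) {
  paste0(x$names, " in [", x$lower, ", ", x$upper, "]", collapse = "; ")
}

is_design_space <- function(x) inherits(x, "design_space")

assert_space <- function(space) {
  if (!is_design_space(space)) stop("'space' must be a design_space object")
  invisible(space)
}

#' Check / coerce a design point against a space
#'
#' @param space A [design_space()].
#' @param x Numeric vector of coordinates, one per variable, in the
#'   variable's native units.
#' @param tol Relative bound tolerance (fraction of each range).
#' @return The coordinates as a named numeric vector.
#' @keywords internal
#' @export
design_point <- function(space, x, tol = 1e-8) {
  assert_space(space)
  x <- as.numeric(x)
  if (length(x) != space$dim)
    stop(sprintf("design point has %d coordinate(s); space has dimension %d",
                 length(x), space$dim))
  slack <- tol * (space$upper - space$lower)
  out <- x < space$lower - slack | x > space$upper + slack
  if (any(out))
    stop("coordinate(s) outside bounds: ", paste(space$names[out], collapse = ", "))
  stats::setNames(x, space$names)
}

## map native units <-> [0,1]^d (kriging and sampling operate on the unit cube)
scale01 <- function(space, X) {
  X <- as_matrix_points(space, X)
  sweep(sweep(X, 2L, space$lower, "-"), 2L, space$upper - space$lower, "/")
}

unscale01 <- function(space, U) {
  U <- as_matrix_points(space, U)
  sweep(sweep(U, 2L, space$upper - space$lower, "*"), 2L, space$lower, "+")
}

as_matrix_points <- function(space, X) {
  if (is.data.frame(X)) X <- as.matrix(X[, space$names, drop = FALSE])
  if (!is.matrix(X)) X <- matrix(as.numeric(X), ncol = space$dim, byrow = FALSE)
  if (ncol(X) != space$dim) stop("point matrix has wrong dimension")
  colnames(X) <- space$names
  X
}

#' Modified-rectangular-grid (MRG) initial sampling design
#'
#' Builds a space-filling initial design for surrogate training: a
#' full-factorial grid whose per-axis level counts give the smallest
#' factorial of at least `n` points, subsampled to exactly `n` points by
#' greedy maximin selection, after which every coordinate lying on a bound
#' is moved into the interior by `shrink` times the variable's range plus
#' a small seeded jitter (at most 1% of the range) that breaks replicated
#' coordinate values. Interior grid points give the surrogate more
#' information than boundary points, and reducing coordinate replication
#' improves the identifiability of anisotropic correlation lengths.
#'
#' @param space A [design_space()].
#' @param n Number of sample points (>= 2).
#' @param shrink Fraction of each variable's range by which boundary
#'   coordinates are moved inward; in `[0, 0.5)`. With `shrink = 0` the
#'   grid is returned unmodified (no move, no jitter).
#' @param seed Integer seed; fixes the design bit-for-bit.
#'
#' @return An object of class `"sample_design"`: list with `space`,
#'   `points` (an `n` x `d` matrix, columns named after the variables) and
#'   `scheme = "mrg"`.
#'
#' @examples
#' sp <- design_space(w1 = c(0.22, 0.34), w2 = c(0.2, 0.3), t1 = c(0.1, 0.14))
#' d <- mrg_design(sp, n = 18, seed = 1)
#' nrow(d$points)
#' @export
mrg_design <- function(space, n, shrink = 0.1, seed = 1L) {
  assert_space(space)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be at least 2")
  if (!is.numeric(shrink) || shrink < 0 || shrink >= 0.5)
    stop("'shrink' must be in [0, 0.5)")
  d <- space$dim
  if (n < 2^d)
    stop(sprintf(paste0("n = %d is too small for a %d-dimensional grid: a ",
                        "factorial grid needs at least 2 levels per axis, ",
                        "i.e. n >= %d (achievable counts: %s, ...)"),
                 n, d, 2^d,
                 paste(vapply(2:4, function(m) 2^(d - 1L) * m, 0), collapse = ", ")))

  levels <- grid_levels(n, d)
  U <- factorial_grid(levels)          # on [0,1]^d
  rng <- local_rng(seed)
  keep <- maximin_subsample(U, n, rng)
  U <- U[keep, , drop = FALSE]

  if (shrink > 0) {
    jit <- matrix(rng$runif(length(U), 0, 0.01), nrow = nrow(U))
    at_lo <- U <= 0 + 1e-12
    at_hi <- U >= 1 - 1e-12
    U[at_lo] <- 0 + shrink + jit[at_lo]
    U[at_hi] <- 1 - shrink - jit[at_hi]
  }

  pts <- unscale01(space, U)
  structure(list(space = space, points = pts, scheme = "mrg",
                 n = n, shrink = shrink, seed = seed),
            class = "sample_design")
}

## smallest full-factorial level vector with product >= n:
## start from ceiling(n^(1/d)) levels everywhere, then greedily drop levels
## on axes while the product stays >= n (never below 2 levels).
grid_levels <- function(n, d) {
  m <- max(2L, as.integer(ceiling(n^(1 / d) - 1e-9)))
  lev <- rep.int(m, d)
  repeat {
    dropped <- FALSE
    for (i in seq_len(d)) {
      if (lev[i] > 2L && prod(lev) * (lev[i] - 1L) / lev[i] >= n) {
        lev[i] <- lev[i] - 1L
        dropped <- TRUE
      }
    }
    if (!dropped) break
  }
  lev
}

factorial_grid <- function(levels) {
  axes <- lapply(levels, function(m) seq(0, 1, length.out = m))
  as.matrix(do.call(expand.grid, axes))
}

## greedy maximin subsample: seed with the point pair at maximum distance,
## then repeatedly add the candidate maximizing its minimum distance to the
## already-selected set; rng breaks exact ties reproducibly.
maximin_subsample <- function(U, n, rng) {
  N <- nrow(U)
  if (n >= N) return(seq_len(N))
  D <- as.matrix(stats::dist(U))
  far <- which(D == max(D), arr.ind = TRUE)[1L, ]
  sel <- c(far[[1L]], far[[2L]])
  mind <- pmin(D[, sel[1L]], D[, sel[2L]])
  while (length(sel) < n) {
    mind[sel] <- -Inf
    best <- max(mind)
    cand <- which(mind >= best - 1e-15)
    pick <- if (length(cand) == 1L) cand else cand[1L + rng$unif_index(length(cand))]
    sel <- c(sel, pick)
    mind <- pmin(mind, D[, pick])
  }
  sel
}

## small self-contained RNG wrapper so package sampling never disturbs the
## caller's .Random.seed
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    runif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    rnorm = function(n) with_state(function() stats::rnorm(n)),
    unif_index = function(n) with_state(function() sample.int(n, 1L)) - 1L,
    derive = function(k) {
      s <- with_state(function() sample.int(2147483646L, 1L))
      (s + 977L * as.integer(k)) %% 2147483647L
    }
  )
}

#' @export
print.sample_design <- function(x, ...) {
  cat(sprintf("%s sample design: %d points in %d-D space\n",
              toupper(x$scheme), nrow(x$points), x$space$dim))
  print(utils::head(as.data.frame(x$points), 6L))
  if (nrow(x$points) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x$points) - 6L))
  invisible(x)
}

#' @export
as.data.frame.sample_design <- function(x, ...) as.data.frame(x$points)

#' Write / read a sample design as CSV
#'
#' Round-trips the point set: header row of variable names, one row per
#' point, '.' decimal separator, no index column.
#'
#' @param design A `sample_design` (or any point matrix with a `space`).
#' @param path File path.
#' @return `write_design_csv` returns `path` invisibly; `read_design_csv`
#'   returns a `sample_design` with scheme `"explicit"`.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design$points), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @param space The design space the points must belong to.
#' @export
read_design_csv <- function(path, space) {
  assert_space(space)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(space$names %in% names(df)))
    stop("CSV is missing variable column(s): ",
         paste(setdiff(space$names, names(df)), collapse = ", "))
  pts <- as_matrix_points(space, df)
  apply(pts, 1L, design_point, space = space)  # validates bounds
  structure(list(space = space, points = pts, scheme = "explicit",
                 n = nrow(pts), shrink = NA_real_, seed = NA_integer_),
            class = "sample_design")
}
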