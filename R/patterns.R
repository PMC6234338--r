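#' 3x3 rotation-task patterns
#'
#' The mental-rotation game presents patterns of filled squares on a 3x3
#' grid. A pattern is represented as a 3x3 logical matrix (`TRUE` = filled).
#' Valid task patterns contain 1--3 four-connected groups of filled cells,
#' are neither empty nor full, and have no rotational symmetry (so that a
#' rotated copy is always distinguishable from the original).
#'
#' @param cells a 3x3 logical matrix, or a length-9 logical/0-1 vector in
#'   row-major order.
#' @return an object of class `pattern3x3`: a 3x3 logical matrix.
#' @examples
#' p <- pattern3x3(c(1,0,0, 1,1,0, 0,0,1))
#' pattern_groups(p)
#' @export
pattern3x3 <- function(cells) {
  if (is.vector(cells)) {
    stopifnot(length(cells) == 9L)
    cells <- matrix(as.logical(cells), nrow = 3L, byrow = TRUE)
  }
  stopifnot(is.matrix(cells), all(dim(cells) == 3L))
  m <- matrix(as.logical(cells), 3L, 3L)
  if (anyNA(m)) stop("pattern cells must be TRUE/FALSE, not NA")
  structure(m, class = c("pattern3x3", class(matrix())))
}

as_pattern <- function(m) structure(m, class = c("pattern3x3", class(matrix())))

#' @export
print.pattern3x3 <- function(x, ...) {
  chars <- ifelse(unclass(x), "#", ".")
  cat(apply(chars, 1L, paste, collapse = ""), sep = "\n")
  invisible(x)
}

#' Rotate a pattern about its center
#'
#' Rotation is clockwise; e.g. the top-left cell moves to the top-right
#' under a 90 degree rotation.
#'
#' @param p a [pattern3x3()].
#' @param deg rotation angle, one of 0, 90, 180, 270.
#' @return the rotated `pattern3x3`; the filled-cell count is preserved.
#' @export
rotate_pattern <- function(p, deg) {
  if (length(deg) != 1L || !deg %in% c(0, 90, 180, 270))
    stop("`deg` must be one of 0, 90, 180, 270")
  m <- unclass(p)
  k <- deg / 90
  for (i in seq_len(k)) m <- t(m[3:1, , drop = FALSE])  # one clockwise quarter turn
  as_pattern(m)
}

#' Reflect a pattern about a mirror axis
#'
#' A vertical axis mirrors left/right (columns reversed); a horizontal
#' axis mirrors top/bottom (rows reversed). Reflecting twice about the
#' same axis is the identity.
#'
#' @param p a [pattern3x3()].
#' @param axis `"vertical"` or `"horizontal"`.
#' @return the reflected `pattern3x3`.
#' @export
reflect_pattern <- function(p, axis = c("vertical", "horizontal")) {
  axis <- match.arg(axis)
  m <- unclass(p)
  m <- if (axis == "vertical") m[, 3:1, drop = FALSE] else m[3:1, , drop = FALSE]
  as_pattern(m)
}

#' Count four-connected groups of filled cells
#'
#' @param p a [pattern3x3()].
#' @return integer number of connected components among filled cells
#'   (edge-adjacency only).
#' @export
pattern_groups <- function(p) {
  m <- unclass(p)
  seen <- matrix(FALSE, 3L, 3L)
  groups <- 0L
  for (r in 1:3) for (c in 1:3) {
    if (m[r, c] && !seen[r, c]) {
      groups <- groups + 1L
      stack <- list(c(r, c))
      while (length(stack)) {
        cell <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        cr <- cell[1L]; cc <- cell[2L]
        if (cr < 1 || cr > 3 || cc < 1 || cc > 3) next
        if (!m[cr, cc] || seen[cr, cc]) next
        seen[cr, cc] <- TRUE
        stack <- c(stack, list(c(cr - 1L, cc), c(cr + 1L, cc),
                               c(cr, cc - 1L), c(cr, cc + 1L)))
      }
    }
  }
  groups
}

pattern_code <- function(p) sum(as.integer(t(unclass(p))) * 2L^(8:0))

pattern_from_code <- function(code) {
  bits <- as.integer(intToBits(code))[9:1]
  pattern3x3(bits)
}

pattern_equal <- function(a, b) identical(unclass(a) * 1L, unclass(b) * 1L)

#' Check a pattern against the task's validity constraints
#'
#' A pattern is task-valid when it has 2--6 filled cells, 1--3
#' four-connected groups, no rotational symmetry, and neither of its axis
#' reflections coincides with any of its nonzero rotations (so that
#' reflection foils can never equal the rotated target).
#'
#' @param p a [pattern3x3()].
#' @return `TRUE` or `FALSE`.
#' @export
pattern_is_valid <- function(p) {
  n <- sum(p)
  if (n < 2L || n > 6L) return(FALSE)
  g <- pattern_groups(p)
  if (g < 1L || g > 3L) return(FALSE)
  rots <- lapply(c(90, 180, 270), function(d) rotate_pattern(p, d))
  if (any(vapply(rots, pattern_equal, logical(1), b = p))) return(FALSE)
  refls <- list(reflect_pattern(p, "vertical"), reflect_pattern(p, "horizontal"))
  for (rf in refls) for (rt in rots)
    if (pattern_equal(rf, rt)) return(FALSE)
  TRUE
}

#' Derive the canonical 18-pattern stimulus set
#'
#' Deterministically enumerates all 512 grids in lexicographic order of
#' their row-major bit code, keeps those passing [pattern_is_valid()],
#' skips any grid rotation-equivalent to one already selected, and stops
#' at 18. This reproduces the packaged fixture exactly.
#'
#' @return list of 18 `pattern3x3` objects.
#' @seealso [load_pattern_set()]
#' @export
derive_pattern_set <- function() {
  out <- list()
  for (code in 1:511) {
    p <- pattern_from_code(code)
    if (!pattern_is_valid(p)) next
    dup <- FALSE
    for (q in out) {
      for (d in c(0, 90, 180, 270)) {
        if (pattern_equal(rotate_pattern(q, d), p)) { dup <- TRUE; break }
      }
      if (dup) break
    }
    if (dup) next
    out[[length(out) + 1L]] <- p
    if (length(out) == 18L) break
  }
  out
}

#' Load the packaged 18-pattern stimulus set
#'
#' Reads the plain-text fixture shipped with the package (18 nine-bit
#' row-major grids, in derivation order) and validates its integrity:
#' exactly 18 patterns, each task-valid, no two rotation-equivalent.
#'
#' @return list of 18 `pattern3x3` objects.
#' @export
load_pattern_set <- function() {
  path <- system.file("extdata", "spin_patterns.json", package = "cogbattery")
  if (path == "") stop("pattern fixture not found; package installation is corrupted")
  bits <- jsonlite::fromJSON(path)
  if (!is.character(bits) || length(bits) != 18L)
    stop("pattern fixture corrupted: expected 18 bit strings")
  pats <- lapply(bits, function(b) {
    v <- as.integer(strsplit(b, "")[[1L]])
    if (length(v) != 9L || anyNA(v) || !all(v %in% 0:1))
      stop("pattern fixture corrupted: malformed bit string '", b, "'")
    pattern3x3(v)
  })
  if (!all(vapply(pats, pattern_is_valid, logical(1))))
    stop("pattern fixture corrupted: invalid pattern present")
  for (i in seq_len(17L)) for (j in (i + 1L):18L) {
    for (d in c(0, 90, 180, 270)) {
      if (pattern_equal(rotate_pattern(pats[[i]], d), pats[[j]]))
        stop("pattern fixture corrupted: patterns ", i, " and ", j,
             " are rotation-equivalent")
    }
  }
  pats
}

#' Build one rotation trial
#'
#' Draws a rotation angle uniformly from 90/180/270 degrees. The correct
#' option is the rotated target; the two foils are the vertical and
#' horizontal reflections of the target. Option order is shuffled.
#'
#' @param p the target [pattern3x3()].
#' @return a list of class `spin_trial` with elements `target`,
#'   `rotation_deg`, `options` (list of 3 patterns) and `correct_index`
#'   (1-based).
#' @export
make_spin_trial <- function(p) {
  rot <- sample(c(90, 180, 270), 1L)
  correct <- rotate_pattern(p, rot)
  foils <- list(reflect_pattern(p, "vertical"), reflect_pattern(p, "horizontal"))
  if (any(vapply(foils, pattern_equal, logical(1), b = correct)))
    stop("foil coincides with correct option; pattern is not task-valid")
  ord <- sample.int(3L)
  options <- vector("list", 3L)
  options[[ord[1L]]] <- correct
  options[[ord[2L]]] <- foils[[1L]]
  options[[ord[3L]]] <- foils[[2L]]
  structure(list(target = p, rotation_deg = rot, options = options,
                 correct_index = ord[1L]),
            class = "spin_trial")
}
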