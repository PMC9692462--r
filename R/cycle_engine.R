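#' Hess's-law identity discovery over a reaction system
#'
#' Each thermochemical quantity is a balanced reaction, i.e. an integer
#' stoichiometric vector over a species set (products positive, reactants
#' negative).  Any rational vector v with `v %*% matrix == 0` is a linear
#' identity that correctly computed quantity values must satisfy exactly
#' (Hess's law).  For the canonical antioxidant system over the species
#' {AXH, AX., AX-, AXH+., H., H+, e-} the left-dependency space has
#' dimension two, and its basis contains (up to sign and scaling) the two
#' pathway identities IP+PDE-PA-ETE = 0 and IP+PDE-BDE-IPH = 0.
#'
#' Basis computation uses exact integer arithmetic throughout (fraction-
#' free elimination); floating point only ever appears when evaluating
#' residuals of measured values.
#'
#' @name cycle_engine
NULL

#' Build a reaction system
#'
#' @param species Character vector of species labels.
#' @param reactions Named list: one entry per quantity, each a named
#'   numeric vector of integer stoichiometric coefficients over (a subset
#'   of) `species`, products positive.
#' @return Object of class `reaction_system` with fields `species`,
#'   `quantities` and the integer `matrix` (quantities x species).
#' @export
reaction_system <- function(species, reactions) {
  species <- as.character(species)
  if (!length(species) || !length(reactions))
    stop("empty reaction system", call. = FALSE)
  if (is.null(names(reactions)) || any(!nzchar(names(reactions))))
    stop("every reaction must be named by its quantity", call. = FALSE)
  M <- matrix(0, nrow = length(reactions), ncol = length(species),
              dimnames = list(names(reactions), species))
  for (q in names(reactions)) {
    r <- reactions[[q]]
    unknown <- setdiff(names(r), species)
    if (length(unknown))
      stop("reaction '", q, "' uses unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (any(r != round(r)))
      stop("stoichiometric coefficients must be integers", call. = FALSE)
    if (all(r == 0))
      stop("reaction '", q, "' is empty", call. = FALSE)
    M[q, names(r)] <- r
  }
  structure(list(species = species, quantities = names(reactions), matrix = M),
            class = "reaction_system")
}

#' The canonical antioxidant reaction system
#'
#' Quantities BDE, IP, PDE, PA, ETE and IPH over the seven species
#' AXH, AX_radical, AX_anion, AXH_cation, H_atom, H_plus, electron.
#'
#' @return A `reaction_system`.
#' @export
canonical_reaction_system <- function() {
  reaction_system(
    species = c("AXH", "AX_radical", "AX_anion", "AXH_cation",
                "H_atom", "H_plus", "electron"),
    reactions = list(
      BDE = c(AXH = -1, AX_radical = 1, H_atom = 1),
      IP  = c(AXH = -1, AXH_cation = 1, electron = 1),
      PDE = c(AXH_cation = -1, AX_radical = 1, H_plus = 1),
      PA  = c(AXH = -1, AX_anion = 1, H_plus = 1),
      ETE = c(AX_anion = -1, AX_radical = 1, electron = 1),
      IPH = c(H_atom = -1, H_plus = 1, electron = 1)
    )
  )
}

# exact integer row reduction: returns list(rref = rational-free integer
# echelon matrix with rows reduced by gcd, pivots = pivot column index per
# row).  Entries stay integral (double-stored); magnitudes remain tiny for
# chemical stoichiometries.
.int_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}
.vec_gcd <- function(v) {
  g <- 0
  for (x in v[v != 0]) g <- .int_gcd(g, x)
  if (g == 0) 1 else g
}

.int_echelon <- function(A) {
  A <- A * 1  # double storage, integer values
  n <- nrow(A); m <- ncol(A)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(m)) {
    if (row > n) break
    p <- which(A[row:n, col] != 0)
    if (!length(p)) next
    p <- p[1] + row - 1L
    if (p != row) A[c(row, p), ] <- A[c(p, row), ]
    for (i in seq_len(n)) {
      if (i != row && A[i, col] != 0) {
        A[i, ] <- A[i, ] * A[row, col] - A[row, ] * A[i, col]
        g <- .vec_gcd(A[i, ])
        A[i, ] <- A[i, ] / g
      }
    }
    g <- .vec_gcd(A[row, ])
    A[row, ] <- A[row, ] / g
    if (A[row, col] < 0) A[row, ] <- -A[row, ]
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(rref = A, pivots = pivots, rank = length(pivots))
}

# reduce a rational vector (given as integer numerator vector + common
# denominator) to primitive integer form with positive leading coefficient
.primitive <- function(v) {
  g <- .vec_gcd(v)
  v <- v / g
  lead <- v[v != 0][1]
  if (lead < 0) v <- -v
  v
}

#' Exact basis of the identity (left-dependency) space
#'
#' Computes `{v : t(v) %*% system$matrix == 0}` by exact integer
#' elimination on the transposed matrix.  Each basis vector is normalized
#' to primitive integer form with positive leading coefficient, and the
#' basis is ordered by lexicographically smallest support.
#'
#' @param system A `reaction_system`.
#' @return Object of class `identity_basis`: list with `quantities` and
#'   `vectors` (matrix, one row per identity, columns = quantities).
#'   Dimension equals `#quantities - rank(matrix)`.
#' @export
identity_basis <- function(system) {
  stopifnot(inherits(system, "reaction_system"))
  # nullspace of t(M): solve t(M) v = 0 for v in R^(#quantities)
  A <- t(system$matrix)
  ech <- .int_echelon(A)
  n <- ncol(A)
  free <- setdiff(seq_len(n), ech$pivots)
  vecs <- matrix(0, nrow = length(free), ncol = n,
                 dimnames = list(NULL, system$quantities))
  if (length(free)) {
    for (k in seq_along(free)) {
      fc <- free[k]
      # rational solution with common denominator = product of pivot values;
      # build with exact integers: v[fc] = prod(pivot entries), back-substitute
      piv_vals <- vapply(seq_along(ech$pivots),
                         function(i) ech$rref[i, ech$pivots[i]], 0)
      denom <- prod(piv_vals)
      v <- numeric(n)
      v[fc] <- denom
      for (i in seq_along(ech$pivots))
        v[ech$pivots[i]] <- -ech$rref[i, fc] * denom / piv_vals[i]
      vecs[k, ] <- .primitive(v)
    }
    ord <- order(apply(vecs, 1, function(v) {
      supp <- which(v != 0)
      paste(sprintf("%03d", supp), collapse = "")
    }))
    vecs <- vecs[ord, , drop = FALSE]
  }
  # exactness guarantee: every vector annihilates the matrix with zero
  # (not merely small) residual
  if (length(free) && any(vecs %*% system$matrix != 0))
    stop("internal error: inexact identity basis", call. = FALSE)
  structure(list(quantities = system$quantities, vectors = vecs,
                 dimension = length(free)), class = "identity_basis")
}

#' @export
print.identity_basis <- function(x, ...) {
  cat("identity basis of dimension", x$dimension, "over",
      paste(x$quantities, collapse = ", "), "\n")
  if (x$dimension) {
    for (i in seq_len(x$dimension)) {
      v <- x$vectors[i, ]
      terms <- sprintf("%+g*%s", v[v != 0], x$quantities[v != 0])
      cat(" ", paste(terms, collapse = " "), "= 0\n")
    }
  }
  invisible(x)
}

#' Check measured quantity values against an identity basis
#'
#' @param values Named numeric vector or list, quantity -> value (one
#'   consistent unit).  Quantities may be missing: identities touching a
#'   missing quantity are reported `indeterminate`.
#' @param basis An `identity_basis`.
#' @param tol Non-negative tolerance; comparison is inclusive.
#' @return data.frame with one row per identity: `identity` (printable
#'   form), `residual`, `tolerance`, `verdict` in
#'   pass / fail / indeterminate.
#' @export
verify_identities <- function(values, basis, tol = 1e-9) {
  stopifnot(inherits(basis, "identity_basis"), tol >= 0)
  values <- unlist(values)
  out <- lapply(seq_len(basis$dimension), function(i) {
    v <- basis$vectors[i, ]
    used <- basis$quantities[v != 0]
    label <- paste(sprintf("%+g*%s", v[v != 0], used), collapse = " ")
    if (!all(used %in% names(values)) ||
        any(!is.finite(values[used]))) {
      return(data.frame(identity = label, residual = NA_real_,
                        tolerance = tol, verdict = "indeterminate",
                        stringsAsFactors = FALSE))
    }
    res <- sum(v[v != 0] * values[used])
    data.frame(identity = label, residual = res, tolerance = tol,
               verdict = if (abs(res) <= tol) "pass" else "fail",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
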