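#' Polarization state conventions
#'
#' The package fixes one Stokes convention throughout: S1 = I_H - I_V,
#' S2 = I_P45 - I_M45, S3 = I_R - I_L with right-circular positive.
#' `stokes_state()` returns the unit-intensity Stokes column vector of a pure
#' polarization state; `analyzer_vector()` returns the row vector of an ideal
#' analyzer for that state, so that the detected intensity behind the analyzer
#' is `analyzer_vector(a) %*% S` for beam Stokes vector `S`.
#'
#' @param state character; one of `"H"`, `"V"`, `"P45"`, `"M45"`, `"R"`, `"L"`.
#' @return `stokes_state()`: numeric length-4 column vector.
#'   `analyzer_vector()`: numeric length-4 row vector (includes the factor 1/2
#'   of an ideal polarizer).
#' @examples
#' stokes_state("R")
#' analyzer_vector("H") %*% stokes_state("H")  # unit transmission
#' @export
stokes_state <- function(state) {
  pol <- switch(match.arg(state, pol_state_names()),
    H   = c(1, 0, 0),
    V   = c(-1, 0, 0),
    P45 = c(0, 1, 0),
    M45 = c(0, -1, 0),
    R   = c(0, 0, 1),
    L   = c(0, 0, -1)
  )
  c(1, pol)
}

#' @rdname stokes_state
#' @export
analyzer_vector <- function(state) {
  0.5 * stokes_state(state)
}

pol_state_names <- function() c("H", "V", "P45", "M45", "R", "L")

#' Design matrix of a generator/analyzer measurement scheme
#'
#' Builds the linear map from the 16 elements of a per-pixel Mueller matrix to
#' the intensities detected for each (generator, analyzer) state pair:
#' `I(g, a) = analyzer_vector(a) %*% M %*% stokes_state(g)`. Row order is the
#' row order of `scheme`; columns follow column-major `vec(M)` so that
#' `intensities = A %*% as.vector(M)`.
#'
#' @param scheme data.frame with character columns `generator` and `analyzer`;
#'   default the minimal invertible 16-state scheme
#'   \{H, V, P45, R\} x \{H, V, P45, R\}.
#' @return list with `A` (n x 16 design matrix) and `scheme`.
#' @export
measurement_scheme <- function(scheme = default_scheme()) {
  stopifnot(is.data.frame(scheme), all(c("generator", "analyzer") %in% names(scheme)))
  A <- t(vapply(seq_len(nrow(scheme)), function(i) {
    g <- stokes_state(scheme$generator[i])
    a <- analyzer_vector(scheme$analyzer[i])
    as.vector(g %x% a)  # kron(t(g), a) row for column-major vec(M)
  }, numeric(16)))
  structure(list(A = A, scheme = scheme), class = "measurement_scheme")
}

default_scheme <- function() {
  st <- c("H", "V", "P45", "R")
  expand.grid(analyzer = st, generator = st,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 2:1]
}
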