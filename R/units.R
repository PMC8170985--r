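#' Unit systems for deck input and output
#'
#' The solver works in SI internally (m, s, kg, Pa). Keyword decks in this
#' field are conventionally written in a mm-ms-kg system, in which stresses
#' come out in GPa and velocities in m/s; that is the default deck unit
#' system. `unit_system()` returns the multiplicative factors that convert
#' deck quantities *into* SI.
#'
#' @param name `"mm-ms-kg"` (default deck convention) or `"si"`.
#' @return An object of class `unit_system`: a list of factors `length`,
#'   `time`, `mass` plus the derived `stress`, `density`, `force`,
#'   `velocity` factors, and the system `name`.
#' @examples
#' u <- unit_system("mm-ms-kg")
#' u$stress   # 1e9: deck stress unit is GPa
#' @export
unit_system <- function(name = c("mm-ms-kg", "si")) {
  name <- match.arg(name)
  base <- switch(name,
    "mm-ms-kg" = list(length = 1e-3, time = 1e-3, mass = 1),
    "si"       = list(length = 1,    time = 1,    mass = 1)
  )
  L <- base$length; T <- base$time; M <- base$mass
  structure(list(
    name = name,
    length = L, time = T, mass = M,
    velocity = L / T,
    acceleration = L / T^2,
    force = M * L / T^2,
    stress = M / (L * T^2),
    density = M / L^3,
    volume = L^3
  ), class = "unit_system")
}

#' @export
print.unit_system <- function(x, ...) {
  cat(sprintf("<unit_system %s> length=%g m, time=%g s, mass=%g kg, stress=%g Pa\n",
              x$name, x$length, x$time, x$mass, x$stress))
  invisible(x)
}
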