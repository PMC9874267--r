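#' Trade-off cost function
#'
#' Proportional life-history cost of a given level of resistance:
#' `c1 * (1 - exp(c2 * r)) / (1 - exp(c2))`. The cost rises from 0 at `r = 0`
#' to `c1` at `r = 1`; positive curvature `c2` gives accelerating
#' (convex) costs, so early resistance is cheap and full resistance expensive.
#' The removable singularity at `c2 = 0` is handled by its analytic limit,
#' the linear cost `c1 * r`.
#'
#' @param r Resistance level(s) in `[0, 1]`.
#' @param c1 Trade-off strength in `[0, 1]`: the maximal proportional cost.
#' @param c2 Trade-off curvature (any real; `> 0` means accelerating costs).
#' @return Numeric cost fraction(s) in `[0, c1]`.
#' @examples
#' tradeoff_cost(0.5, c1 = 0.5, c2 = 3)
#' @export
tradeoff_cost <- function(r, c1, c2) {
  if (any(r < 0 | r > 1)) {
    abort("resistance r must lie in [0, 1]", class = "ageresist_param_error")
  }
  if (any(c1 < 0 | c1 > 1)) {
    abort("trade-off strength c1 must lie in [0, 1]",
          class = "ageresist_param_error")
  }
  gen <- c1 * (1 - exp(c2 * r)) / (1 - exp(c2))
  lin <- rep_len(c1 * r, length(gen))
  ifelse(rep_len(abs(c2) < 1e-12, length(gen)), lin, gen)
}

# Effective life-history rates for one parameter list, at resistance (rJ, rA)
# overriding the resident traits when given. Applies the cost to exactly the
# wired trait(s); a double reproduction wiring multiplies the cost factors;
# mortality wiring increases b (cost enters as 1 + cost).
effective_rates_list <- function(p, rJ = p$rJ, rA = p$rA) {
  cj <- tradeoff_cost(rJ, p$c1J, p$c2J)
  ca <- tradeoff_cost(rA, p$c1A, p$c2A)
  a <- p$a0
  g <- p$g0
  bJ <- p$b0
  bA <- p$b0
  switch(p$juvenile_target,
         maturation = g <- p$g0 * (1 - cj),
         reproduction = a <- a * (1 - cj),
         juvenile_mortality = bJ <- p$b0 * (1 + cj))
  switch(p$adult_target,
         reproduction = a <- a * (1 - ca),
         adult_mortality = bA <- p$b0 * (1 + ca))
  list(a = a, g = g, bJ = bJ, bA = bA,
       betaJ = p$beta0 * (1 - rJ), betaA = p$beta0 * (1 - rA))
}

host_viable <- function(e) e$a * e$g > e$bA * (e$bJ + e$g)

#' Effective (trade-off-modified) life-history rates
#'
#' Applies the trade-off costs implied by the wiring and the resident
#' resistance traits, returning the realised reproduction (`a`), maturation
#' (`g`), mortality (`bJ`, `bA`) and transmission (`betaJ`, `betaA`) rates.
#' Traits not wired to a resistance trait keep their baseline values; when
#' both resistance traits are wired to reproduction the two cost factors
#' multiply; mortality costs add to the baseline mortality.
#'
#' @param params A `host_params` tibble (any number of rows).
#' @return The input with columns `a`, `g`, `bJ`, `bA`, `betaJ`, `betaA`
#'   appended (one set per row).
#' @examples
#' host_params(adult_target = "reproduction", rA = 1) |> effective_rates()
#' @export
effective_rates <- function(params) {
  validate_params(params)
  eff <- purrr::map(seq_len(nrow(params)),
                    function(i) as_tibble(effective_rates_list(plist(params, i))))
  dplyr::bind_cols(as_tibble(params), dplyr::bind_rows(eff))
}
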