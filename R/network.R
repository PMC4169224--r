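#' Define a degradation reaction
#'
#' A reaction consumes one particle of its substrate per firing and releases
#' product species in fixed fractional amounts. For `kinetics = "monod"` the
#' rate is \eqn{a = \mu_{max} S/(K + S) \cdot X} where `S` is the substrate
#' count, `X` the degrader (biomass) count and `K` the half-saturation
#' constant; the degrader acts as a catalyst and grows by its yield fraction,
#' which must be included in `products` so that the fractions close to 1.
#' `kinetics = "linear"` gives the mass-action rate \eqn{a = \mu_{max} S}
#' with no degrader; it exists for test fixtures with closed-form solutions
#' (pure death, isomerization) and is exempt from the mass-closure rule.
#'
#' @param name reaction identifier.
#' @param substrate name of the consumed species (coefficient 1 per firing).
#' @param degrader name of the catalysing biomass species, or `NA` for
#'   linear kinetics.
#' @param mu_max maximum specific uptake rate (1/day for monod kinetics;
#'   per-particle rate constant for linear kinetics).
#' @param K half-saturation constant, concentration units (ignored for
#'   linear kinetics).
#' @param products named numeric vector: fraction of each consumed substrate
#'   unit appearing as each product (for monod reactions this includes the
#'   degrader's biomass yield and the fractions must sum to 1).
#' @param kinetics `"monod"` (default) or `"linear"`.
#' @param inhibition optional non-competitive inhibition, a list with
#'   elements `inhibitor` (species name) and `K_I` (> 0, concentration
#'   units); multiplies the base rate by \eqn{K_I/(K_I + I)}.
#' @param second_substrate optional dual-substrate Monod factor, a list with
#'   elements `name` (species) and `K2` (> 0); multiplies the base rate by
#'   \eqn{S_2/(K_2 + S_2)}.
#' @return an object of class `ad_reaction`.
#' @seealso [reaction_network()], [build_ad_network()]
#' @export
reaction <- function(name, substrate, degrader, mu_max, K, products,
                     kinetics = c("monod", "linear"),
                     inhibition = NULL, second_substrate = NULL) {
  kinetics <- match.arg(kinetics)
  if (!is.numeric(products) || is.null(names(products)) ||
      any(!nzchar(names(products)))) {
    if (length(products) == 0L) {
      products <- stats::setNames(numeric(0), character(0))
    } else {
      stop("'products' must be a named numeric vector", call. = FALSE)
    }
  }
  structure(
    list(name = as.character(name),
         substrate = as.character(substrate),
         degrader = if (is.na(degrader)) NA_character_ else as.character(degrader),
         mu_max = as.numeric(mu_max),
         K = as.numeric(K),
         products = products,
         kinetics = kinetics,
         inhibition = inhibition,
         second_substrate = second_substrate),
    class = "ad_reaction")
}

#' Assemble a reaction network
#'
#' @param species data frame with columns `name` and `role`
#'   (`"substrate_product"` or `"degrader"`), or a character vector of names
#'   (all taken as `substrate_product`).
#' @param reactions list of [reaction()] objects.
#' @param name optional network label.
#' @return an object of class `ad_network`: the species table, the reaction
#'   list and the net stoichiometry matrix `stoich` (species x reactions;
#'   -1 for the substrate, + the fraction for each product).
#' @details Construction only requires that every referenced species is
#'   registered and unique; quantitative invariants (positivity, fraction
#'   ranges, mass closure) are checked by [validate_network()], which
#'   reports rather than throws.
#' @export
reaction_network <- function(species, reactions, name = "network") {
  if (is.character(species)) {
    species <- data.frame(name = species, role = "substrate_product")
  }
  stopifnot(is.data.frame(species), all(c("name", "role") %in% names(species)))
  species$name <- as.character(species$name)
  species$role <- as.character(species$role)
  if (anyDuplicated(species$name)) {
    stop("duplicate species names: ",
         paste(unique(species$name[duplicated(species$name)]), collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(species$role, c("substrate_product", "degrader"))
  if (length(bad_role)) {
    stop("unknown species role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  if (!is.list(reactions) || !all(vapply(reactions, inherits, TRUE, "ad_reaction"))) {
    stop("'reactions' must be a list of reaction() objects", call. = FALSE)
  }
  rnames <- vapply(reactions, `[[`, "", "name")
  if (anyDuplicated(rnames)) stop("duplicate reaction names", call. = FALSE)
  for (r in reactions) {
    refs <- c(r$substrate, if (!is.na(r$degrader)) r$degrader, names(r$products),
              r$inhibition$inhibitor, r$second_substrate$name)
    unknown <- setdiff(refs, species$name)
    if (length(unknown)) {
      stop("reaction '", r$name, "' references unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  net <- structure(
    list(name = name, species = species, reactions = reactions,
         stoich = NULL),
    class = "ad_network")
  net$stoich <- stoich_matrix(net)
  net
}

#' Net stoichiometry matrix of a network
#'
#' One column per reaction: -1 for the substrate, plus the product fraction
#' for every product (the degrader's biomass yield among them). For monod
#' reactions each column sums to zero, which is the conservation law behind
#' the mass-closure rule.
#'
#' @param net an `ad_network`.
#' @return numeric matrix, species (rows) x reactions (columns), dimnames set.
#' @export
stoich_matrix <- function(net) {
  sp <- net$species$name
  nu <- matrix(0, nrow = length(sp), ncol = length(net$reactions),
               dimnames = list(sp, vapply(net$reactions, `[[`, "", "name")))
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    nu[r$substrate, j] <- nu[r$substrate, j] - 1
    for (p in names(r$products)) nu[p, j] <- nu[p, j] + r$products[[p]]
  }
  nu
}

#' The anaerobic digestion default network
#'
#' Builds the 11-species, 5-reaction network describing the degradation of
#' glucose to methane by four microbial groups: glucose fermentation to
#' butyrate, propionate, acetate and hydrogen (r1); butyrate (r2) and
#' propionate (r3) oxidation to acetate and hydrogen; acetoclastic (r4) and
#' hydrogenotrophic (r5) methanogenesis. Product fractions are the published
#' stoichiometric constants of the ADM1-derived sub-model; each degrader's
#' biomass yield is obtained by mass closure (one minus the sum of the
#' reaction's product fractions), giving yields 0.100, 0.060, 0.040, 0.050
#' and 0.060 for r1..r5.
#'
#' Kinetic parameters (1/day and concentration units):
#' \tabular{lll}{
#'   reaction \tab mu_max \tab K \cr
#'   r1 glucose \tab 1.25 \tab 500 \cr
#'   r2 butyrate \tab 0.833 \tab 200 \cr
#'   r3 propionate \tab 0.542 \tab 100 \cr
#'   r4 acetate \tab 0.333 \tab 150 \cr
#'   r5 hydrogen \tab 0.35 \tab 150
#' }
#'
#' @return an `ad_network`.
#' @examples
#' net <- build_ad_network()
#' colSums(net$stoich)       # all zero: mass closure
#' @export
build_ad_network <- function() {
  species <- data.frame(
    name = c("glucose", "butyrate", "propionate", "acetate", "hydrogen",
             "methane", "sugar_degraders", "butyrate_degraders",
             "propionate_degraders", "acetate_degraders", "hydrogen_degraders"),
    role = c(rep("substrate_product", 6), rep("degrader", 5)))
  reactions <- list(
    reaction("r1", "glucose", "sugar_degraders", 1.25, 500,
             c(butyrate = 0.117, propionate = 0.243, acetate = 0.369,
               hydrogen = 0.171, sugar_degraders = 0.100)),
    reaction("r2", "butyrate", "butyrate_degraders", 0.833, 200,
             c(acetate = 0.752, hydrogen = 0.188, butyrate_degraders = 0.060)),
    reaction("r3", "propionate", "propionate_degraders", 0.542, 100,
             c(acetate = 0.5472, hydrogen = 0.4128, propionate_degraders = 0.040)),
    reaction("r4", "acetate", "acetate_degraders", 0.333, 150,
             c(methane = 0.95, acetate_degraders = 0.05)),
    reaction("r5", "hydrogen", "hydrogen_degraders", 0.35, 150,
             c(methane = 0.94, hydrogen_degraders = 0.06)))
  reaction_network(species, reactions, name = "ad_default")
}

#' Validate a reaction network
#'
#' Checks the structural and quantitative invariants of a network and
#' returns a report instead of throwing: unknown species references,
#' non-positive `mu_max` or `K`, product fractions outside (0, 1], a
#' substrate listed among its own products, and (for monod reactions) mass
#' closure — product fractions, biomass yield included, must sum to 1 within
#' `1e-9`, equivalently the stoichiometry column must sum to 0.
#'
#' @param net an `ad_network` (or a structurally similar list).
#' @return a data frame of class `ad_validation` with columns `reaction`,
#'   `check` and `message`; zero rows means the network is valid.
#' @export
validate_network <- function(net) {
  issues <- list()
  add <- function(reaction, check, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      reaction = reaction, check = check, message = message)
  }
  sp <- net$species$name
  if (anyDuplicated(sp)) {
    add(NA_character_, "species_unique", "duplicate species names")
  }
  for (r in net$reactions) {
    refs <- c(substrate = r$substrate,
              if (!is.na(r$degrader)) c(degrader = r$degrader),
              stats::setNames(names(r$products), rep("product", length(r$products))))
    for (i in seq_along(refs)) {
      if (!refs[[i]] %in% sp) {
        add(r$name, "unknown_species",
            sprintf("%s '%s' is not a registered species", names(refs)[i], refs[[i]]))
      }
    }
    if (!is.finite(r$mu_max) || r$mu_max <= 0) {
      add(r$name, "positivity", sprintf("mu_max = %g is not > 0", r$mu_max))
    }
    if (identical(r$kinetics, "monod") && (!is.finite(r$K) || r$K <= 0)) {
      add(r$name, "positivity", sprintf("K = %g is not > 0", r$K))
    }
    bad <- r$products[r$products <= 0 | r$products > 1]
    for (p in names(bad)) {
      add(r$name, "fraction_range",
          sprintf("product fraction %s = %g outside (0, 1]", p, bad[[p]]))
    }
    if (r$substrate %in% names(r$products)) {
      add(r$name, "self_product",
          sprintf("substrate '%s' appears among its own products", r$substrate))
    }
    if (identical(r$kinetics, "monod")) {
      tot <- sum(r$products)
      if (abs(tot - 1) > 1e-9) {
        add(r$name, "closure",
            sprintf("product fractions sum to %.10f, not 1 (|diff| = %.3g)",
                    tot, abs(tot - 1)))
      }
    }
    if (!is.null(r$inhibition) &&
        (!is.finite(r$inhibition$K_I) || r$inhibition$K_I <= 0)) {
      add(r$name, "positivity", "inhibition constant K_I is not > 0")
    }
  }
  rep <- if (length(issues)) do.call(rbind, issues) else
    data.frame(reaction = character(), check = character(), message = character())
  class(rep) <- c("ad_validation", "data.frame")
  rep
}

#' Convert concentrations to particle counts
#'
#' Applies the system-size factor Omega: each species' particle count is its
#' concentration times `omega` (the "1:5" rule corresponds to `omega = 5`).
#' Half-saturation constants are interpreted on the same scaled axis inside
#' the propensity kernel (`K_scaled = K * omega`), so the Monod fraction
#' `S/(K + S)` is invariant under the choice of Omega while absolute rates
#' scale linearly with it.
#'
#' @param conc named numeric vector of concentrations (>= 0), names matching
#'   network species.
#' @param omega system-size factor, particles per concentration unit (> 0).
#' @param net optional `ad_network`; when given, the result is expanded and
#'   ordered to the network's full species list (missing species get 0).
#' @return named numeric vector of particle counts.
#' @export
concentration_to_particles <- function(conc, omega, net = NULL) {
  if (!is.numeric(conc) || is.null(names(conc))) {
    stop("'conc' must be a named numeric vector", call. = FALSE)
  }
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0) {
    stop("'omega' must be a single value > 0", call. = FALSE)
  }
  x <- conc * omega
  if (!is.null(net)) {
    unknown <- setdiff(names(x), net$species$name)
    if (length(unknown)) {
      stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    full <- stats::setNames(numeric(nrow(net$species)), net$species$name)
    full[names(x)] <- x
    x <- full
  }
  x
}

#' @export
print.ad_network <- function(x, ...) {
  cat(sprintf("<ad_network '%s'>: %d species, %d reactions\n",
              x$name, nrow(x$species), length(x$reactions)))
  for (r in x$reactions) {
    prods <- paste(sprintf("%.4g %s", r$products, names(r$products)),
                   collapse = " + ")
    kin <- if (identical(r$kinetics, "monod"))
      sprintf("monod(mu_max=%.4g, K=%.4g, X=%s)", r$mu_max, r$K, r$degrader)
    else sprintf("linear(c=%.4g)", r$mu_max)
    cat(sprintf("  %s: %s -> %s   [%s]\n", r$name, r$substrate, prods, kin))
  }
  invisible(x)
}

#' @export
print.ad_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("network valid: no violations\n")
  } else {
    cat(sprintf("%d violation(s):\n", nrow(x)))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.ad_network <- function(object, ...) {
  cs <- colSums(object$stoich)
  cat(sprintf("Network '%s': %d species (%d degraders), %d reactions\n",
              object$name, nrow(object$species),
              sum(object$species$role == "degrader"), length(object$reactions)))
  cat("stoichiometry column sums (0 = mass closure):\n")
  print(round(cs, 12))
  v <- validate_network(object)
  print(v)
  invisible(list(column_sums = cs, validation = v))
}
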