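#' Read a reaction network from a config file
#'
#' Accepts YAML (`.yml`/`.yaml`) or JSON (`.json`) with top-level keys
#' `species` (list of `{name, role}`) and `reactions` (list of
#' `{name, substrate, degrader, mu_max, K, products, kinetics, inhibition,
#' second_substrate}`). The shipped digestion network is installed at
#' `system.file("extdata", "ad_network.yaml", package = "adsim")` as a
#' template. The parsed network is validated automatically; any violation
#' is an error listing all of them.
#'
#' @param path config file path.
#' @return a validated `ad_network`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- tryCatch(
    if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
    else yaml::read_yaml(path),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(cfg) || !is.list(cfg) ||
      is.null(cfg$species) || is.null(cfg$reactions)) {
    stop("cannot parse '", path,
         "': expected top-level keys 'species' and 'reactions'", call. = FALSE)
  }
  species <- data.frame(
    name = vapply(cfg$species, function(s) as.character(s$name), ""),
    role = vapply(cfg$species, function(s)
      as.character(s$role %||% "substrate_product"), ""))
  reactions <- lapply(cfg$reactions, function(r) {
    prods <- unlist(r$products)
    reaction(name = r$name, substrate = r$substrate,
             degrader = r$degrader %||% NA_character_,
             mu_max = r$mu_max, K = r$K %||% 1,
             products = if (length(prods)) prods else
               stats::setNames(numeric(0), character(0)),
             kinetics = r$kinetics %||% "monod",
             inhibition = r$inhibition,
             second_substrate = r$second_substrate)
  })
  net <- reaction_network(species, reactions,
                          name = cfg$name %||% tools::file_path_sans_ext(basename(path)))
  v <- validate_network(net)
  if (nrow(v)) {
    stop("invalid network '", path, "':\n",
         paste(sprintf("  [%s/%s] %s", v$reaction, v$check, v$message),
               collapse = "\n"), call. = FALSE)
  }
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a reaction network to a config file
#'
#' Inverse of [read_network()]; format chosen from the file extension
#' (YAML default, JSON for `.json`).
#'
#' @param net an `ad_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  cfg <- list(
    name = net$name,
    species = lapply(seq_len(nrow(net$species)), function(i)
      list(name = net$species$name[i], role = net$species$role[i])),
    reactions = lapply(net$reactions, function(r) {
      out <- list(name = r$name, substrate = r$substrate,
                  degrader = if (is.na(r$degrader)) NULL else r$degrader,
                  mu_max = r$mu_max, K = r$K,
                  products = as.list(r$products),
                  kinetics = r$kinetics)
      if (!is.null(r$inhibition)) out$inhibition <- r$inhibition
      if (!is.null(r$second_substrate)) out$second_substrate <- r$second_substrate
      out
    }))
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path, precision = 15)
  }
  invisible(path)
}

#' Write a trajectory (or ensemble) to CSV
#'
#' Trajectories are written as `time,<species...>,clamps` with one row per
#' grid time (the clamp count, a run-level total, is repeated per row for a
#' self-contained file). Ensembles are written as
#' `time,<species>_mean...,<species>_var...`. Values are written at full
#' precision so a read-back reproduces the numbers exactly.
#'
#' @param traj an `ad_trajectory` or `ad_ensemble`.
#' @param path output CSV path.
#' @param manifest write a JSON run manifest next to the CSV
#'   (`<path>.manifest.json`)? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, manifest = TRUE) {
  if (inherits(traj, "ad_ensemble")) {
    df <- data.frame(time = traj$times, check.names = FALSE)
    for (s in colnames(traj$mean)) df[[paste0(s, "_mean")]] <- traj$mean[, s]
    for (s in colnames(traj$variance)) df[[paste0(s, "_var")]] <- traj$variance[, s]
  } else {
    df <- data.frame(time = traj$times, traj$state, check.names = FALSE)
    df$clamps <- traj$clamps
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = ","), con)
  body <- do.call(paste, c(lapply(df, format_full), list(sep = ",")))
  writeLines(body, con)
  if (manifest) write_manifest(traj, paste0(path, ".manifest.json"))
  invisible(path)
}

format_full <- function(x) {
  if (is.numeric(x)) formatC(x, digits = 17, format = "g") else as.character(x)
}

#' Read back a trajectory CSV
#'
#' @param path CSV written by [write_trajectory()].
#' @return list with `times`, `state` (matrix) and `clamps` (or `NA` if the
#'   file has no clamp column).
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  clamps <- if ("clamps" %in% names(df)) df$clamps[1L] else NA_integer_
  keep <- setdiff(names(df), c("time", "clamps"))
  list(times = df$time,
       state = as.matrix(df[, keep, drop = FALSE]),
       clamps = clamps)
}

#' Run manifest
#'
#' A small JSON record written alongside every output file: the config echo
#' (method, tau, t_end, record_dt, seed, replicates, omega), an MD5 checksum
#' of the canonical network serialization, the package version and a wall
#' start timestamp. Re-running with an identical manifest (same network,
#' config and seed) reproduces identical stochastic output.
#'
#' @param traj an `ad_trajectory` or `ad_ensemble`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(traj, path) {
  cfg <- traj$cfg
  man <- list(
    method = cfg$method, tau = cfg$tau, t_end = cfg$t_end,
    record_dt = cfg$record_dt, seed = cfg$seed, replicates = cfg$replicates,
    omega = cfg$omega,
    network = if (!is.null(traj$network)) traj$network else NA,
    clamps = traj$clamps,
    artifact_version = as.character(utils::packageVersion("adsim")),
    wall_start = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Network checksum
#'
#' MD5 checksum of the canonical JSON serialization of a network, used in
#' run manifests and logs to pin which network produced an output.
#'
#' @param net an `ad_network`.
#' @return character MD5 string.
#' @export
network_checksum <- function(net) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_network(net, tf)
  unname(tools::md5sum(tf))
}

#' Built-in test fixtures
#'
#' Small networks with closed-form behaviour, used as simulation oracles:
#' \describe{
#'   \item{`pure_death`}{one species `A`, one linear reaction with
#'     per-particle rate `c` (propensity `c * N`, no products): particle
#'     count decays with mean `N0 * exp(-c t)` and binomial-survival
#'     variance, and the state distribution solves a 1D master equation.}
#'   \item{`isomerization`}{two species `A + B` with linear exchange rates
#'     `k_AB`, `k_BA`; the stationary count of `A` is
#'     binomial(`N`, `k_BA/(k_AB + k_BA)`).}
#'   \item{`ad_default`}{[build_ad_network()] with the documented initial
#'     state from [ad_initial_state()] at the given `omega`.}
#' }
#'
#' @param kind one of `"pure_death"`, `"isomerization"`, `"ad_default"`.
#' @param N0 initial particle count (pure death / isomerization).
#' @param c per-particle death rate (pure death).
#' @param k_AB,k_BA exchange rates (isomerization).
#' @param omega system-size factor (ad_default).
#' @return list with elements `network` and `init`.
#' @export
make_fixture <- function(kind = c("pure_death", "isomerization", "ad_default"),
                         N0 = 100, c = 0.1, k_AB = 1, k_BA = 1, omega = 1) {
  if (is.character(kind) && length(kind) == 1L &&
      !kind %in% c("pure_death", "isomerization", "ad_default")) {
    stop("unknown fixture kind '", kind, "'", call. = FALSE)
  }
  kind <- match.arg(kind)
  switch(kind,
    pure_death = {
      net <- reaction_network(
        data.frame(name = "A", role = "substrate_product"),
        list(reaction("death", "A", NA, mu_max = c, K = 1,
                      products = stats::setNames(numeric(0), character(0)),
                      kinetics = "linear")),
        name = "pure_death")
      list(network = net, init = c(A = N0))
    },
    isomerization = {
      net <- reaction_network(
        data.frame(name = c("A", "B"),
                   role = c("substrate_product", "substrate_product")),
        list(reaction("AtoB", "A", NA, mu_max = k_AB, K = 1,
                      products = c(B = 1), kinetics = "linear"),
             reaction("BtoA", "B", NA, mu_max = k_BA, K = 1,
                      products = c(A = 1), kinetics = "linear")),
        name = "isomerization")
      list(network = net, init = c(A = N0, B = 0))
    },
    ad_default = list(network = build_ad_network(),
                      init = ad_initial_state(omega)))
}
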