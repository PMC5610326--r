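# Configuration handling and result serialization for command-line runs.

#' Validate and normalize a run configuration
#'
#' Configuration schema (YAML/JSON):
#' \preformatted{
#' lipid: DOPC                    # registry name, or a parameter block:
#' # lipid: {name: custom, B_kBT: 10, KA_mN_per_m: 120,
#' #         Kt_mN_per_m: 40, h_nm: 1.5, J0_per_nm: -0.05}
#' environment: {sigma0_mN_per_m: 0, sigma_h_mN_per_m: 36, xi_h_nm: 1}
#' scan: {r_min: 0.1, r_max: 50, r_points: 0,   # 0 = default grid
#'        hydrophobic: yes}
#' output: {dir: "poredge-out", plots: no}
#' }
#'
#' @param config a list (parsed YAML/JSON) or a path to a YAML file.
#' @return validated `run_config` object with `lipid`
#'   ([lipid_parameters()]), `env` ([environment_parameters()]), `scan`,
#'   `output` entries.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  bad <- function(field, why) stop("invalid config field '", field, "': ", why,
                                   call. = FALSE)
  lip <- config$lipid
  if (is.null(lip)) bad("lipid", "missing (registry name or parameter block)")
  lipid <- if (is.character(lip)) get_lipid(lip)
  else {
    need <- c("B_kBT", "KA_mN_per_m", "h_nm")
    miss <- setdiff(need, names(lip))
    if (length(miss)) bad("lipid", paste("missing", paste(miss, collapse = ", ")))
    lipid_parameters(if (is.null(lip$name)) "custom" else lip$name,
                     B_kBT = lip$B_kBT, KA_mN_per_m = lip$KA_mN_per_m,
                     Kt_mN_per_m = if (is.null(lip$Kt_mN_per_m)) 40 else lip$Kt_mN_per_m,
                     h_nm = lip$h_nm,
                     J0_per_nm = if (is.null(lip$J0_per_nm)) 0 else lip$J0_per_nm)
  }
  ev <- config$environment
  env <- environment_parameters(
    sigma0_mN_per_m = if (is.null(ev$sigma0_mN_per_m)) 0 else ev$sigma0_mN_per_m,
    sigma_h_mN_per_m = if (is.null(ev$sigma_h_mN_per_m)) 36 else ev$sigma_h_mN_per_m,
    xi_h_nm = if (is.null(ev$xi_h_nm)) 1 else ev$xi_h_nm)
  sc <- config$scan
  scan <- list(r_min = if (is.null(sc$r_min)) 0.1 else sc$r_min,
               r_max = if (is.null(sc$r_max)) 50 else sc$r_max,
               r_points = if (is.null(sc$r_points)) 0 else sc$r_points,
               hydrophobic = if (is.null(sc$hydrophobic)) TRUE else isTRUE(sc$hydrophobic))
  if (!is.numeric(scan$r_min) || scan$r_min <= 0) bad("scan.r_min", "must be > 0")
  if (!is.numeric(scan$r_max) || scan$r_max <= scan$r_min) bad("scan.r_max", "must exceed r_min")
  out <- config$output
  output <- list(dir = if (is.null(out$dir)) "poredge-out" else out$dir,
                 plots = isTRUE(out$plots))
  structure(list(lipid = lipid, env = env, scan = scan, output = output),
            class = "run_config")
}

.fmt_num <- function(x) formatC(x, format = "g", digits = 9)

#' Write trajectory results (CSV, feature JSON, manifest)
#'
#' Serializes a computed trajectory deterministically (9 significant digits,
#' fixed column order): `trajectory.csv` (per-radius results),
#' `features.json` (landscape features), and `manifest.json` (parameters
#' and versions used).
#'
#' @param traj `pore_trajectory`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_trajectory <- function(traj, dir) {
  stopifnot(inherits(traj, "pore_trajectory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pts <- traj$points
  csv <- file.path(dir, "trajectory.csv")
  out <- data.frame(r_nm = .fmt_num(pts$r),
                    regime = pts$regime,
                    L_opt_nm = .fmt_num(pts$L_opt),
                    W_kBT = .fmt_num(pts$W),
                    gamma_pN = .fmt_num(pts$gamma_pN),
                    R0_nm = .fmt_num(pts$R0),
                    Z0_nm = .fmt_num(pts$Z0))
  utils::write.csv(out, csv, row.names = FALSE, quote = FALSE)
  fjson <- file.path(dir, "features.json")
  jsonlite::write_json(traj$features, fjson, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  man <- file.path(dir, "manifest.json")
  lp <- traj$lipid; ev <- traj$env
  manifest <- list(
    lipid = list(name = lp$name, B_kBT = lp$B,
                 KA_mN_per_m = tension_to_mN_per_m(lp$K_A),
                 Kt_mN_per_m = tension_to_mN_per_m(lp$K_t),
                 h_nm = lp$h, J0_per_nm = lp$J0,
                 registry = lp$name %in% list_lipids()),
    environment = list(sigma0_mN_per_m = tension_to_mN_per_m(ev$sigma0),
                       sigma_h_mN_per_m = tension_to_mN_per_m(ev$sigma_h),
                       xi_h_nm = ev$xi_h),
    kBT_joules = kBT_joules,
    versions = list(poredge = as.character(utils::packageVersion("poredge")),
                    R = paste(R.version$major, R.version$minor, sep = "."))
  )
  jsonlite::write_json(manifest, man, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, fjson, man))
}

#' Read a feature JSON written by [write_trajectory()]
#' @param path file path.
#' @return list of features.
#' @export
read_features <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Run a trajectory computation from a configuration
#'
#' The deterministic pipeline behind the `trajectory` CLI subcommand:
#' validates the configuration, computes the optimal trajectory and writes
#' `trajectory.csv`, `features.json` and `manifest.json` to the output
#' directory.
#'
#' @param config list, `run_config`, or YAML path.
#' @return the `pore_trajectory`, invisibly; files on disk as side effect.
#' @export
run_trajectory_command <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  grid <- if (cfg$scan$r_points > 0)
    exp(seq(log(cfg$scan$r_min), log(cfg$scan$r_max), length.out = cfg$scan$r_points))
  else NULL
  traj <- optimal_trajectory(cfg$lipid, cfg$env, r_grid = grid,
                             r_max = cfg$scan$r_max,
                             hydrophobic = cfg$scan$hydrophobic)
  write_trajectory(traj, cfg$output$dir)
  invisible(traj)
}

#' Export the edge shape profile of an optimized pore geometry
#'
#' Writes the neutral-surface profile of both regions (wall and surrounding
#' bilayer) for a junction-optimized pore, as used for edge-shape figures.
#'
#' @param lipid,env,r,L,mode as in [optimize_junction()].
#' @param path output CSV path (columns: region, coord_nm, shape_nm —
#'   for the wall: z and R(z); for the bilayer: rho and H(rho)).
#' @param n points per region.
#' @return invisibly, the data.frame written.
#' @export
export_edge_shape <- function(lipid, env, r, L = 0,
                              mode = c("hydrophilic", "hydrophobic"),
                              path, n = 120) {
  mode <- match.arg(mode)
  opt <- optimize_junction(lipid, env, r, L, mode, breakdown = TRUE)
  bd <- opt$breakdown
  g <- opt$geometry
  z <- seq(if (mode == "hydrophobic") L else 0, g$Z0, length.out = n)
  mf <- monolayer_fields(bd$monolayer, z)
  rho <- seq(g$R0, g$R0 + 12, length.out = n)
  bf <- bilayer_fields(bd$bilayer, rho)
  out <- rbind(data.frame(region = "wall", coord_nm = .fmt_num(mf$z),
                          shape_nm = .fmt_num(mf$R)),
               data.frame(region = "bilayer", coord_nm = .fmt_num(bf$rho),
                          shape_nm = .fmt_num(bf$H)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
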