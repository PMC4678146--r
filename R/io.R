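# Readers/writers for trajectories, fates and run manifests. Plain CSV and
# JSON throughout; times are serialised as decimal floating point with 12
# significant digits and counts as integers.

fmt_time <- function(x) ifelse(is.na(x), "NA", sprintf("%.12g", x))

#' Write / read a trajectory CSV
#'
#' Columns: \code{t,n_total,N_surviving,phi_bar,C_bar,deaths,divisions,
#' thymic_arrivals}. Counts are written as integers, times and means with 12
#' significant digits.
#'
#' @param trajectory data frame as returned in
#'   \code{\link{run_simulation}()$trajectory}.
#' @param path file path.
#' @return \code{write_trajectory} returns \code{path} invisibly;
#'   \code{read_trajectory} returns the data frame.
#' @export
write_trajectory <- function(trajectory, path) {
  out <- data.frame(
    t = fmt_time(trajectory$t),
    n_total = as.integer(trajectory$n_total),
    N_surviving = as.integer(trajectory$N_surviving),
    phi_bar = fmt_time(trajectory$phi_bar),
    C_bar = fmt_time(trajectory$C_bar),
    deaths = as.integer(trajectory$deaths),
    divisions = as.integer(trajectory$divisions),
    thymic_arrivals = as.integer(trajectory$thymic_arrivals))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  read.csv(path, colClasses = c(
    t = "numeric", n_total = "integer", N_surviving = "integer",
    phi_bar = "numeric", C_bar = "numeric", deaths = "integer",
    divisions = "integer", thymic_arrivals = "integer"))
}

#' Write / read a clonotype-fates CSV
#'
#' Columns: \code{clonotype_id,t_birth,t_extinction,censored,phi,max_size};
#' \code{t_extinction} is empty (NA) for clonotypes still alive at the
#' horizon (\code{censored} TRUE).
#'
#' @param fates data frame as returned in
#'   \code{\link{run_simulation}()$fates}.
#' @param path file path.
#' @export
write_fates <- function(fates, path) {
  out <- data.frame(
    clonotype_id = as.integer(fates$clonotype_id),
    t_birth = fmt_time(fates$t_birth),
    t_extinction = fmt_time(fates$t_extinction),
    censored = fates$censored,
    phi = as.integer(fates$phi),
    max_size = as.integer(fates$max_size))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fates
#' @export
read_fates <- function(path) {
  read.csv(path, colClasses = c(
    clonotype_id = "integer", t_birth = "numeric", t_extinction = "numeric",
    censored = "logical", phi = "integer", max_size = "integer"))
}

run_manifest <- function(params, experiment, files, started, finished) {
  list(experiment = experiment,
       params = unclass(params)[setdiff(names(unclass(params)), "seeds")],
       seeds = params$seeds,
       software = list(package = "clonedyn",
                       version = as.character(packageVersion("clonedyn"))),
       started = started, finished = finished,
       files = lapply(files, function(f)
         list(name = basename(f), md5 = unname(tools::md5sum(f)))))
}

#' Write all outputs of a simulation to a directory
#'
#' Writes the trajectory CSV, the fates CSV, the network edge list and JSON
#' sidecar, and a run manifest (resolved parameters, seed set, software
#' version, wall-clock interval and an MD5-checksummed file inventory). The
#' manifest plus the package version suffice to reproduce every output.
#'
#' @param sim a \code{repertoire_sim}.
#' @param out_dir output directory (created if needed).
#' @param name stem used for the file names.
#' @return invisibly, the named vector of written file paths.
#' @export
write_outputs <- function(sim, out_dir, name = "run") {
  stopifnot(inherits(sim, "repertoire_sim"))
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    trajectory = file.path(out_dir, paste0(name, "_trajectory.csv")),
    fates = file.path(out_dir, paste0(name, "_fates.csv")),
    network_edges = file.path(out_dir, paste0(name, "_network_edges.csv")),
    network_meta = file.path(out_dir, paste0(name, "_network_meta.json")))
  write_trajectory(sim$trajectory, paths[["trajectory"]])
  write_fates(sim$fates, paths[["fates"]])
  write_network(sim$network, paths[["network_edges"]], paths[["network_meta"]])
  manifest <- run_manifest(sim$params, "simulate", unname(paths), started,
                           format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mpath <- file.path(out_dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, manifest = mpath))
}
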