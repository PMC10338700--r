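#' Input/output file formats
#'
#' The planner's inputs are organised as four CSV files plus one plain-text
#' configuration per site and wave:
#' \itemize{
#'   \item \code{state.csv} — one row per cluster x band: \code{cluster_id},
#'     \code{rank}, \code{band}, \code{eligible} (n_jk),
#'     \code{invited_prop} (a_jk), \code{booked} (t_jk).
#'   \item \code{costs.csv} — \code{cluster_id}, \code{band}, \code{cost},
#'     \code{event_rate}.
#'   \item \code{uptake.csv} — \code{cluster_id}, \code{band}, \code{uptake}.
#'   \item \code{optout.csv} — \code{cluster_id}, \code{optout_factor}.
#'   \item \code{config.txt} — \code{key: value} lines: \code{slots},
#'     \code{round} (1-4), \code{uptake_adjustment} (default 1.0).
#' }
#' The output is a single request CSV with columns \code{cluster_id},
#' \code{age_band}, \code{sex}, \code{requested_count}; rows with zero
#' requests are suppressed and rows are sorted by cluster id then band, so
#' identical inputs always produce byte-identical files.
#'
#' @name io_formats
NULL

bundle_files <- c(state = "state.csv", costs = "costs.csv",
                  uptake = "uptake.csv", optout = "optout.csv",
                  config = "config.txt")

require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema error in ", basename(file), ": missing column(s) ",
         paste(missing, collapse = ", "))
}

#' Read a site input bundle
#'
#' Reads the four CSV input files and the TXT configuration from a directory,
#' checks cross-file consistency (same cluster set, same band range), and
#' assembles the planning objects.
#'
#' @param dir Directory containing \code{state.csv}, \code{costs.csv},
#'   \code{uptake.csv}, \code{optout.csv} and \code{config.txt}.
#' @param scheme A \code{group_scheme}; band indices in the files must lie in
#'   1..K.
#' @return List with \code{site} (planning object with \code{n}, \code{rank},
#'   \code{e}, \code{u}, \code{optout}, \code{costs}), \code{state} (a
#'   \code{site_state}), and \code{config}.
#' @export
read_bundle <- function(dir, scheme = group_scheme()) {
  paths <- file.path(dir, bundle_files)
  names(paths) <- names(bundle_files)
  for (p in paths) if (!file.exists(p)) stop("missing input file: ", p)
  K <- scheme$K
  st <- utils::read.csv(paths["state"], stringsAsFactors = FALSE)
  require_columns(st, c("cluster_id", "rank", "band", "eligible",
                        "invited_prop", "booked"), paths["state"])
  co <- utils::read.csv(paths["costs"], stringsAsFactors = FALSE)
  require_columns(co, c("cluster_id", "band", "cost", "event_rate"),
                  paths["costs"])
  up <- utils::read.csv(paths["uptake"], stringsAsFactors = FALSE)
  require_columns(up, c("cluster_id", "band", "uptake"), paths["uptake"])
  oo <- utils::read.csv(paths["optout"], stringsAsFactors = FALSE)
  require_columns(oo, c("cluster_id", "optout_factor"), paths["optout"])
  config <- read_config(paths["config"])

  ids <- sort(unique(st$cluster_id))
  for (nm in c("costs", "uptake", "optout")) {
    other <- switch(nm, costs = co, uptake = up, optout = oo)
    if (!setequal(unique(other$cluster_id), ids))
      stop("consistency error: cluster set in ", bundle_files[nm],
           " differs from state.csv")
  }
  for (df in list(st, co, up)) {
    if (any(!df$band %in% seq_len(K)))
      stop("band indices must lie in 1..", K)
  }
  J <- length(ids)
  tomat <- function(df, col) {
    m <- matrix(NA_real_, J, K)
    m[cbind(match(df$cluster_id, ids), df$band)] <- df[[col]]
    if (anyNA(m)) stop("consistency error: incomplete cluster x band grid for ", col)
    m
  }
  n <- tomat(st, "eligible"); a <- tomat(st, "invited_prop")
  t_jk <- tomat(st, "booked")
  e <- tomat(co, "event_rate"); cmat <- tomat(co, "cost")
  u <- tomat(up, "uptake")
  rank <- unname(vapply(ids, function(id) st$rank[match(id, st$cluster_id)],
                        numeric(1)))
  optout <- unname(vapply(ids, function(id)
    oo$optout_factor[match(id, oo$cluster_id)], numeric(1)))
  if (any(optout < 1)) stop("optout_factor must be >= 1")
  if (any(n < 0)) stop("eligible counts must be non-negative")
  if (any(a < 0 | a > 1)) stop("invited proportions must lie in [0, 1]")
  wave <- config$round
  state <- site_state(config$slots, J, K, ledger = t_jk, invited = a,
                      wave = wave)
  site <- list(ids = ids, rank = as.integer(rank), n = n, optout = optout,
               e = e, u = u, costs = structure(list(c = cmat),
                                               class = "cost_matrix"),
               scheme = scheme)
  list(site = site, state = state, config = config)
}

#' Read the plain-text wave configuration
#'
#' \code{key: value} lines; recognised keys are \code{slots} (positive
#' integer), \code{round} (1-4) and \code{uptake_adjustment} (positive real,
#' default 1.0). Blank lines and lines starting with \code{#} are ignored.
#'
#' @param path Path to the configuration file.
#' @param max_round Largest admissible invitation round.
#' @return List with \code{slots}, \code{round}, \code{uptake_adjustment}.
#' @export
read_config <- function(path, max_round = 4L) {
  lines <- readLines(path, warn = FALSE)
  vals <- list(uptake_adjustment = 1.0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    m <- regmatches(ln, regexec("^([A-Za-z_ ]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("parse error in ", basename(path), " line ", i, ": ", ln)
    key <- gsub(" ", "_", tolower(trimws(m[2])))
    val <- suppressWarnings(as.numeric(trimws(m[3])))
    if (is.na(val))
      stop("parse error in ", basename(path), " line ", i,
           ": non-numeric value for ", key)
    vals[[key]] <- val
  }
  if (is.null(vals$slots) || vals$slots <= 0 || vals$slots != round(vals$slots))
    stop("config: slots must be a positive integer")
  if (is.null(vals$round) || !vals$round %in% seq_len(max_round))
    stop("config: round must be one of 1..", max_round)
  if (vals$uptake_adjustment <= 0)
    stop("config: uptake_adjustment must be positive")
  list(slots = as.integer(vals$slots), round = as.integer(vals$round),
       uptake_adjustment = vals$uptake_adjustment)
}

#' Write a site input bundle
#'
#' Inverse of \code{\link{read_bundle}}: writes the four CSVs and the TXT
#' configuration for a site at a given wave. Rows are sorted by cluster id
#' and band so output is canonical.
#'
#' @param site A site planning object (needs \code{ids}, \code{rank},
#'   \code{n}, \code{optout}, \code{e}, \code{u} and optionally
#'   \code{costs}).
#' @param state A \code{site_state}.
#' @param dir Output directory (created if needed).
#' @param uptake_adjustment Value written to the configuration.
#' @return Invisibly, the directory.
#' @export
write_bundle <- function(site, state, dir, uptake_adjustment = 1.0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  K <- ncol(site$n); J <- nrow(site$n)
  ord <- order(site$ids)
  grid <- expand.grid(band = seq_len(K), j = ord)[, c(2, 1)]
  st <- data.frame(cluster_id = site$ids[grid$j],
                   rank = site$rank[grid$j],
                   band = grid$band,
                   eligible = site$n[cbind(grid$j, grid$band)],
                   invited_prop = state$invited[cbind(grid$j, grid$band)],
                   booked = state$ledger[cbind(grid$j, grid$band)])
  utils::write.csv(st, file.path(dir, "state.csv"), row.names = FALSE,
                   quote = FALSE)
  cmat <- if (!is.null(site$costs)) site$costs$c else
    compute_costs(site$e, site$rank)$c
  co <- data.frame(cluster_id = site$ids[grid$j], band = grid$band,
                   cost = cmat[cbind(grid$j, grid$band)],
                   event_rate = site$e[cbind(grid$j, grid$band)])
  utils::write.csv(co, file.path(dir, "costs.csv"), row.names = FALSE,
                   quote = FALSE)
  up <- data.frame(cluster_id = site$ids[grid$j], band = grid$band,
                   uptake = site$u[cbind(grid$j, grid$band)])
  utils::write.csv(up, file.path(dir, "uptake.csv"), row.names = FALSE,
                   quote = FALSE)
  oo <- data.frame(cluster_id = site$ids[ord],
                   optout_factor = site$optout[ord])
  utils::write.csv(oo, file.path(dir, "optout.csv"), row.names = FALSE,
                   quote = FALSE)
  writeLines(c(paste0("slots: ", format(state$capacity, scientific = FALSE)),
               paste0("round: ", state$wave),
               paste0("uptake_adjustment: ", uptake_adjustment)),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' Write the invitation request CSV
#'
#' One row per (cluster, age band, sex) with a positive request; zero rows
#' are suppressed. Rows are sorted by cluster id then band index, numerics
#' are unquoted and the file is UTF-8, so identical inputs give byte-identical
#' output.
#'
#' @param requests J x K integer matrix of invitation requests.
#' @param ids Cluster identifiers (length J).
#' @param scheme A \code{group_scheme}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_request_csv <- function(requests, ids, scheme, path) {
  requests <- as.matrix(requests)
  if (any(requests < 0) || any(requests != round(requests)))
    stop("requests must be non-negative integers")
  J <- nrow(requests); K <- ncol(requests)
  ord <- order(ids)
  rows <- expand.grid(band = seq_len(K), j = ord)
  cnt <- requests[cbind(rows$j, rows$band)]
  keep <- cnt > 0
  df <- data.frame(cluster_id = ids[rows$j][keep],
                   age_band = scheme$age_labels[scheme$age_band[rows$band]][keep],
                   sex = scheme$sex[rows$band][keep],
                   requested_count = as.integer(cnt[keep]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an invitation request CSV back into a matrix
#'
#' @param path Request CSV path.
#' @param ids Cluster identifiers defining the row order.
#' @param scheme A \code{group_scheme}.
#' @return J x K integer matrix.
#' @export
read_request_csv <- function(path, ids, scheme) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("cluster_id", "age_band", "sex", "requested_count"),
                  path)
  K <- scheme$K; H <- K / 2L
  band <- match(df$age_band, scheme$age_labels) +
    ifelse(df$sex == "F", H, 0L)
  if (anyNA(band)) stop("unknown age band or sex label in ", basename(path))
  j <- match(df$cluster_id, ids)
  if (anyNA(j)) stop("unknown cluster id in ", basename(path))
  m <- matrix(0L, length(ids), K)
  m[cbind(j, band)] <- as.integer(df$requested_count)
  m
}
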