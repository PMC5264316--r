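#' Write an ensemble archive to aligned CSV files
#'
#' Writes `S.csv` (decision matrix, one column per member), `O.csv`
#' (objective matrix) and `R.csv` (rank vector), plus optional
#' `run_metadata.json` echoing the run configuration.
#'
#' @param archive An [ensemble_archive].
#' @param dir Output directory (created when missing).
#' @param metadata Optional named list serialized to
#'   `run_metadata.json`.
#' @return The directory path, invisibly.
#' @export
save_archive <- function(archive, dir, metadata = NULL) {
  stopifnot(inherits(archive, "ensemble_archive"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(archive$S, file.path(dir, "S.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(archive$O, file.path(dir, "O.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(matrix(archive$R, ncol = 1L), file.path(dir, "R.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  if (!is.null(metadata)) {
    metadata$r_version <- as.character(getRversion())
    jsonlite::write_json(metadata, file.path(dir, "run_metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(dir)
}

read_archive_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(lines))) return(matrix(numeric(0), 0, 0))
  m <- as.matrix(utils::read.table(text = lines, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  m
}

#' Load an ensemble archive written by [save_archive()]
#'
#' @param dir Directory containing aligned `S.csv`, `O.csv` and `R.csv`.
#' @return An [ensemble_archive]; the round trip through CSV reproduces
#'   the archive exactly up to numeric printing precision.
#' @export
load_archive <- function(dir) {
  S <- read_archive_matrix(file.path(dir, "S.csv"))
  O <- read_archive_matrix(file.path(dir, "O.csv"))
  R <- read_archive_matrix(file.path(dir, "R.csv"))
  if (ncol(S) != ncol(O) || (length(R) > 0L && length(R) != ncol(O))) {
    stop("archive files in ", dir, " are misaligned")
  }
  dimnames(S) <- NULL
  dimnames(O) <- NULL
  ensemble_archive(S, O, as.integer(R))
}

#' Write synthetic training datasets as tidy CSV
#'
#' Long format with columns `dataset_id`, `time`, `species`, `value`.
#'
#' @param datasets List from [generate_synthetic_datasets()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_datasets <- function(datasets, path) {
  rows <- lapply(datasets, function(d) {
    do.call(rbind, lapply(colnames(d$y), function(sp) {
      data.frame(dataset_id = d$dataset_id, time = d$times, species = sp,
                 value = d$y[, sp])
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read tidy-CSV training datasets written by [write_datasets()]
#'
#' @param path CSV path.
#' @return List of datasets in the [generate_synthetic_datasets()] layout
#'   (without generating parameters).
#' @export
read_datasets <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("dataset_id", "time", "species", "value") %in% names(df)))
  lapply(sort(unique(df$dataset_id)), function(id) {
    sub <- df[df$dataset_id == id, ]
    times <- sort(unique(sub$time))
    species <- unique(sub$species)
    y <- sapply(species, function(sp) {
      s <- sub[sub$species == sp, ]
      s$value[match(times, s$time)]
    })
    list(dataset_id = id, times = times,
         y = matrix(y, nrow = length(times),
                    dimnames = list(NULL, species)))
  })
}

#' Reshape a simulated trajectory to tidy long form
#'
#' @param sim Trajectory data.frame from [simulate_hcm()].
#' @return A data.frame with columns `time`, `species`, `value`.
#' @export
tidy_trajectory <- function(sim) {
  species <- setdiff(names(sim), "time")
  out <- do.call(rbind, lapply(species, function(sp) {
    data.frame(time = sim$time, species = sp, value = sim[[sp]])
  }))
  rownames(out) <- NULL
  out
}

#' Export a network and its elementary modes as JSON
#'
#' @param modes An `elementary_modes` set.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_modes_json <- function(modes, path) {
  net <- modes$network
  payload <- list(
    species = rownames(net$sigma),
    internal = net$internal,
    reactions = colnames(net$sigma),
    stoichiometry = unname(apply(net$sigma, 2, as.numeric, simplify = FALSE)),
    mode_count = modes$L,
    modes = lapply(seq_len(modes$L), function(l) {
      list(fluxes = as.numeric(modes$Z[, l]),
           growth_flux = modes$z_mu[l],
           uptake_flux = modes$z_s[l],
           substrate = if (is.na(modes$substrate[l])) NULL else
             modes$substrate[l])
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
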