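# Delimited-text and config I/O. Numeric columns are written with 17
# significant digits so that TSV round-trips reproduce doubles exactly.

fmt_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

write_tsv_full <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_full), stringsAsFactors = FALSE,
                       check.names = FALSE)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write / read a labeling dataset
#'
#' Serialises a dataset as a TSV (`subset`, `time_days`, `mouse_id`,
#' `labeled_count`, `total_count`) plus a JSON sidecar (`<path>.json`)
#' holding the per-subset ranges and, for synthetic data, the generating
#' provenance (true parameters, topology, design, noise, seed). The
#' round trip is lossless.
#'
#' @param data A `bk_dataset` from [generate_dataset()].
#' @param path Path of the TSV file to write (sidecar is `<path>.json`).
#' @return `path`, invisibly (`write`); a `bk_dataset` (`read`).
#' @export
write_labeling_dataset <- function(data, path) {
  write_tsv_full(as_tibble(data), path)
  side <- list(ranges = attr(data, "ranges"),
               provenance = attr(data, "provenance"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_labeling_dataset
#' @export
read_labeling_dataset <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          subset = readr::col_character(),
                          time_days = readr::col_double(),
                          mouse_id = readr::col_integer(),
                          labeled_count = readr::col_double(),
                          total_count = readr::col_double()
                        ))
  out <- structure(as_tibble(df), class = c("bk_dataset", class(tibble())))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$ranges)) attr(out, "ranges") <- as_tibble(side$ranges)
    if (!is.null(side$provenance)) attr(out, "provenance") <- side$provenance
  }
  out
}

#' Write / read a model configuration
#'
#' One YAML file describes one model: the bone-marrow parameters, the
#' splenic parameters and the topology (direction plus edge flags). The
#' round trip is stable.
#'
#' @param p,q,topo Parameters and topology to serialise.
#' @param path YAML file path.
#' @return `path`, invisibly (`write`); a list with elements `p`, `q`,
#'   `topo` (`read`).
#' @export
write_model_config <- function(p, q, topo, path) {
  p <- as_bm_parameters(p)
  q <- as_spleen_parameters(q)
  cfg <- list(
    bone_marrow = plain(p),
    spleen = plain(q),
    topology = list(direction = topo$direction,
                    edges = as.list(topo$edges))
  )
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  topo <- do.call(model_topology,
                  c(list(direction = cfg$topology$direction),
                    cfg$topology$edges))
  list(
    p = as_bm_parameters(cfg$bone_marrow),
    q = as_spleen_parameters(cfg$spleen),
    topo = topo
  )
}

#' Write a time course as TSV
#'
#' @param course A `bk_timecourse` or `bk_labeled_timecourse`.
#' @param path TSV file path.
#' @return `path`, invisibly.
#' @export
write_timecourse_tsv <- function(course, path) {
  write_tsv_full(as_tibble(course), path)
}
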