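#' Read and write aligned binding sites as FASTA
#'
#' The description line carries the site id and optional
#' `autoregulated=true` key. Sequences are wrapped at 60 columns on
#' output.
#'
#' @param path file path.
#' @return `read_sites_fasta()`: a data.frame with columns `site_id`,
#'   `sequence`, `autoregulated`.
#' @export
read_sites_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  auto <- grepl("autoregulated=true", hdr, fixed = TRUE)
  id <- vapply(strsplit(hdr, "\\s+"), `[`, character(1), 1)
  data.frame(site_id = id, sequence = as.character(ss),
             autoregulated = auto, row.names = NULL)
}

#' @rdname read_sites_fasta
#' @param sites named character vector of sequences.
#' @param autoregulated optional logical vector marking sites.
#' @export
write_sites_fasta <- function(sites, path, autoregulated = NULL) {
  ss <- Biostrings::DNAStringSet(unname(sites))
  nm <- if (is.null(names(sites))) paste0("site_", seq_along(sites))
        else names(sites)
  if (!is.null(autoregulated))
    nm <- ifelse(autoregulated, paste(nm, "autoregulated=true"), nm)
  names(ss) <- nm
  Biostrings::writeXStringSet(ss, path, width = 60)
  invisible(path)
}

#' Tab-separated table IO
#'
#' Thin wrappers fixing the dialect used throughout: tab separator,
#' header row, `.` decimal, no quoting, no row names.
#'
#' @param path file path.
#' @param x a data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read model parameters from a config file
#'
#' JSON (`.json`) or YAML (`.yml`/`.yaml`) with keys matching
#' [tcs_params()] fields (normalized values), or dimensional values plus
#' a `K_auto` key, in which case [normalize_params()] is applied.
#' `overrides` (e.g. from CLI flags) replace file values before
#' construction. A `full_rates` subsection, if present, is returned as a
#' [full_tcs_rates()] object.
#'
#' @param path config file path.
#' @param overrides named list of replacement values.
#' @return A list with `params` (a `tcs_params`), `rates`
#'   (`tcs_full_rates` or `NULL`) and `raw` (the merged key list).
#' @export
read_config <- function(path, overrides = list()) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(cfg)) stop("configuration error: config must be a mapping")
  rates_cfg <- cfg$full_rates
  cfg$full_rates <- NULL
  cfg <- modifyList(cfg, overrides)
  params <- if (!is.null(cfg$K_auto) &&
                (is.null(cfg$normalized) || !isTRUE(cfg$normalized))) {
    normalize_params(cfg[setdiff(names(cfg), c("K_auto", "normalized"))],
                     K_auto = cfg$K_auto)
  } else {
    keep <- intersect(names(cfg),
                      c("f", "h", "Rb", "D", "K", "l", "Cp", "Ct",
                        "K_auto", "k_dil", "alpha"))
    do.call(tcs_params, cfg[keep])
  }
  rates <- if (!is.null(rates_cfg)) do.call(full_tcs_rates, rates_cfg)
           else NULL
  list(params = params, rates = rates, raw = cfg)
}

#' Write a JSON metadata sidecar next to an output file
#'
#' Records the effective parameter set, assumptions (e.g. the `Ct* = 3`
#' convention), tolerances and the seed, so every emitted table is
#' auditable.
#'
#' @param meta named list.
#' @param out_path path of the main output; the sidecar gets
#'   `.meta.json` appended.
#' @return The sidecar path, invisibly.
#' @export
write_metadata <- function(meta, out_path) {
  side <- paste0(out_path, ".meta.json")
  meta$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  meta$package_version <- as.character(utils::packageVersion("tcsgain"))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(side)
}
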