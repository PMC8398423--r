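#' Multi-environment trial dataset
#'
#' Container for long-format plot-level records of a multi-environment trial
#' (MET).  Each record is one plot measurement: trial year, location, the
#' environment key (`year::location`), replicate, optional incomplete block,
#' genotype, trait, and the measured value.  The constructor validates the
#' records and builds ordered registries of environments, genotypes, and
#' traits.
#'
#' @param records data.frame with columns `year`, `location`, `environment`,
#'   `replicate`, `block` (optional, may be `NA`), `genotype`, `trait`,
#'   `value`.  If `environment` is missing it is derived as
#'   `year::location`.
#' @return An object of class `met_dataset`: a list with elements `records`,
#'   `environments`, `genotypes`, `traits`.
#' @export
met_dataset <- function(records) {
  records <- as.data.frame(records)
  if (!"environment" %in% names(records) &&
      all(c("year", "location") %in% names(records))) {
    records$environment <- paste0(records$year, "::", records$location)
  }
  needed <- c("year", "location", "environment", "replicate", "genotype",
              "trait", "value")
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    stop("records lack required column(s): ", paste(miss, collapse = ", "))
  }
  if (!"block" %in% names(records)) records$block <- NA_integer_
  if (!is.numeric(records$value)) {
    stop("value column must be numeric")
  }
  bad <- which(!is.na(records$value) & !is.finite(records$value))
  if (length(bad)) {
    stop("non-finite value in row ", bad[1])
  }
  key <- paste(records$environment, records$genotype, records$replicate,
               records$trait, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    d <- which(dup)[1]
    stop(sprintf(
      "duplicate plot record for (environment=%s, genotype=%s, replicate=%s, trait=%s)",
      records$environment[d], records$genotype[d], records$replicate[d],
      records$trait[d]))
  }
  front <- c("year", "location", "environment", "replicate", "block",
             "genotype", "trait", "value")
  records <- records[, c(front, setdiff(names(records), front)), drop = FALSE]
  structure(list(
    records = records,
    environments = sort(unique(records$environment)),
    genotypes = sort(unique(records$genotype)),
    traits = sort(unique(records$trait))
  ), class = "met_dataset")
}

#' @export
print.met_dataset <- function(x, ...) {
  cat(sprintf(
    "met_dataset: %d plot records | %d environments x %d genotypes | traits: %s\n",
    nrow(x$records), length(x$environments), length(x$genotypes),
    paste(x$traits, collapse = ", ")))
  invisible(x)
}

#' Number of environments / genotypes in a dataset
#' @param dataset a [met_dataset()].
#' @return integer count.
#' @export
n_environments <- function(dataset) length(dataset$environments)

#' @rdname n_environments
#' @export
n_genotypes <- function(dataset) length(dataset$genotypes)

#' Read / write MET plot records as CSV
#'
#' The CSV dialect is comma-separated with a `.` decimal mark, a header with
#' exactly the plot-record field names (`year, location, environment,
#' replicate, block, genotype, trait, value`), UTF-8 encoding, and empty
#' cells for missing values.  Unknown extra columns are preserved as opaque
#' metadata.  Reading a written dataset returns identical records.
#'
#' @param path file path.
#' @return `read_met_csv` returns a [met_dataset()]; `write_met_csv`
#'   (invisibly) returns `path`.
#' @export
read_met_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!"value" %in% names(raw)) stop("CSV lacks a 'value' column")
  if (is.character(raw$value)) {
    conv <- suppressWarnings(as.numeric(raw$value))
    bad <- which(!is.na(raw$value) & raw$value != "" & is.na(conv))
    if (length(bad)) {
      stop("non-numeric value in data row ", bad[1], ": '",
           raw$value[bad[1]], "'")
    }
    raw$value <- conv
  }
  met_dataset(raw)
}

#' @rdname read_met_csv
#' @param dataset a [met_dataset()].
#' @export
write_met_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "met_dataset"))
  utils::write.csv(dataset$records, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict a dataset to one trait / a set of environments
#'
#' @param dataset a [met_dataset()].
#' @param trait trait name.
#' @param environments environment keys to keep.
#' @return A [met_dataset()] with the matching records.
#' @export
subset_trait <- function(dataset, trait) {
  stopifnot(inherits(dataset, "met_dataset"))
  if (!trait %in% dataset$traits) {
    stop("trait '", trait, "' not present in dataset")
  }
  met_dataset(dataset$records[dataset$records$trait == trait, , drop = FALSE])
}

#' @rdname subset_trait
#' @export
subset_environments <- function(dataset, environments) {
  stopifnot(inherits(dataset, "met_dataset"))
  keep <- dataset$records$environment %in% environments
  if (!any(keep)) stop("no records left after environment subset")
  met_dataset(dataset$records[keep, , drop = FALSE])
}

#' Grain yield from ear weight
#'
#' Converts plot ear weight to grain yield in kg/ha at a standard 15%
#' moisture basis, assuming an 80% shelling percentage:
#' \deqn{yield = ear\_weight \times 0.80 \times \frac{100 - moisture}{100 - 15}
#'   \times \frac{10000}{plot\_area}}
#'
#' @param ear_weight_kg_per_plot harvested ear weight per plot, kg.
#' @param grain_moisture_pct grain moisture at harvest, percent (0 to <100).
#' @param plot_area_m2 harvested plot area in square metres (e.g. a single
#'   5 m row at 0.75 m spacing = 3.75 m2).
#' @param shelling_pct shelling percentage (default 80).
#' @param target_moisture_pct moisture basis of the reported yield
#'   (default 15).
#' @return Grain yield in kg/ha.
#' @export
yield_from_ear_weight <- function(ear_weight_kg_per_plot, grain_moisture_pct,
                                  plot_area_m2, shelling_pct = 80,
                                  target_moisture_pct = 15) {
  if (any(ear_weight_kg_per_plot < 0)) stop("ear weight must be >= 0")
  if (any(grain_moisture_pct < 0 | grain_moisture_pct >= 100)) {
    stop("grain moisture must be in [0, 100)")
  }
  if (any(plot_area_m2 <= 0)) stop("plot area must be > 0")
  ear_weight_kg_per_plot * (shelling_pct / 100) *
    (100 - grain_moisture_pct) / (100 - target_moisture_pct) *
    10000 / plot_area_m2
}
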