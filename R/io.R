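# mechanism codes used in gene-origin tables: duplication vs de novo origins
MECHANISM_CODES <- c(D = "duplication", Dl = "duplication",
                     R = "duplication", Rl = "duplication",
                     A = "de_novo", Al = "de_novo")

#' Read a genes-by-tissues expression matrix
#'
#' Delimited text with a header row: first column gene id, remaining
#' columns tissues; `NA` marks missing expression.
#'
#' @param path file path.
#' @param sep field separator, default `","`.
#' @return numeric matrix with gene rownames and tissue colnames.
#' @export
read_expression <- function(path, sep = ",") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  if (ncol(df) < 2) stop("expression table needs a gene column plus tissues: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated gene ids in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read a gene age / origination-mechanism table
#'
#' Delimited text with columns gene id, branch (integer 0-13), mechanism
#' code. Codes `D`, `Dl`, `R`, `Rl` mean duplication; `A`, `Al` mean de
#' novo origination; the long forms `duplication` / `de_novo` /
#' `ancestral` are also accepted. Genes with an empty mechanism are treated
#' as de novo (unknown origin defaults to de novo).
#'
#' @param path file path.
#' @param sep field separator, default `","`.
#' @param header whether the file has a header row (default TRUE).
#' @return data frame with columns `gene`, `branch`, `new_branch` (the 7-
#'   branch repartition of `branch`), `mechanism`.
#' @export
read_ages <- function(path, sep = ",", header = TRUE) {
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, colClasses = "character",
                          comment.char = "")
  if (ncol(df) < 3) stop("age table needs gene, branch, mechanism columns: ", path)
  names(df)[1:3] <- c("gene", "branch", "mechanism")
  offset <- if (header) 1L else 0L
  if (anyDuplicated(df$gene)) {
    stop("duplicated gene ids in ", path, ": ",
         paste(utils::head(unique(df$gene[duplicated(df$gene)]), 5), collapse = ", "))
  }
  branch <- suppressWarnings(as.integer(df$branch))
  bad <- which(is.na(branch) | branch < 0 | branch > 13)
  if (length(bad)) {
    stop("invalid branch (must be an integer 0-13) at line ",
         bad[1] + offset, " of ", path, ": '", df$branch[bad[1]], "'")
  }
  mech_in <- trimws(df$mechanism)
  mech <- ifelse(mech_in == "", "de_novo",
          ifelse(mech_in %in% names(MECHANISM_CODES), MECHANISM_CODES[mech_in],
          ifelse(mech_in %in% c("duplication", "de_novo", "ancestral"),
                 mech_in, NA_character_)))
  bad <- which(is.na(mech))
  if (length(bad)) {
    stop("unknown mechanism code at line ", bad[1] + offset, " of ", path,
         ": '", mech_in[bad[1]], "' (legal codes: ",
         paste(names(MECHANISM_CODES), collapse = ", "),
         ", duplication, de_novo, ancestral)")
  }
  data.frame(gene = df$gene, branch = branch,
             new_branch = new_branch_of(branch),
             mechanism = unname(mech), stringsAsFactors = FALSE)
}

#' Read a run configuration
#'
#' YAML configuration holding any of the evolution parameters (`alpha`,
#' `beta`, `gamma`, `delta`, `r_dup`, `r_novo`), the `model`, a `schedule`
#' (list of `[n_dup, n_novo]` pairs, durations, or counts, depending on the
#' model), `threshold`, `replicates` and `seed`.
#'
#' @param path YAML file path.
#' @return named list with a validated `params` ([evolution_params()])
#'   element merged over the defaults.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files")
  }
  cfg <- yaml::read_yaml(path)
  par_fields <- intersect(c("alpha", "beta", "gamma", "delta", "r_dup", "r_novo"),
                          names(cfg))
  cfg$params <- do.call(evolution_params, cfg[par_fields])
  if (!is.null(cfg$model) &&
      !cfg$model %in% c("model1", "model2", "traditional")) {
    stop("model must be one of model1, model2, traditional")
  }
  if (!is.null(cfg$threshold) && (cfg$threshold <= 0 || cfg$threshold >= 1)) {
    stop("threshold must be in (0, 1)")
  }
  cfg
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seed and package version of a run as JSON so
#' that any output can be regenerated byte-identically.
#'
#' @param path output file path.
#' @param ... named fields to record (e.g. seed, model, schedule, counts).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, ...) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the 'jsonlite' package is required to write manifests")
  }
  fields <- list(...)
  fields$package_version <- as.character(utils::packageVersion("coevonet"))
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
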