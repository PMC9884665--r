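#' Read an assay design from a JSON or YAML configuration file
#'
#' The configuration holds named arguments of [assay_design()] (unknown keys
#' are rejected). Format is chosen by extension: \code{.json} via jsonlite,
#' \code{.yml}/\code{.yaml} via the yaml package.
#'
#' @param path Path to a \code{.json}, \code{.yml} or \code{.yaml} file.
#' @return An [assay_design()].
#' @export
read_design <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml = ,
    yaml = {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configuration requires the 'yaml' package",
             call. = FALSE)
      }
      yaml::read_yaml(path)
    },
    stop("unsupported configuration format: .", ext, call. = FALSE)
  )
  unknown <- setdiff(names(cfg), names(formals(assay_design)))
  if (length(unknown)) {
    stop("unknown design field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(assay_design, cfg)
}
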