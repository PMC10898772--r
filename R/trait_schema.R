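#' Bundled morphological character schema
#'
#' The default schema of 35 characters used for feathergrass hybrid
#' morphometrics: 29 quantitative characters (measured in millimeters, or
#' unitless ratios) and 6 qualitative characters with integer-coded levels.
#'
#' @return a \code{trait_schema}: data frame with columns \code{code},
#'   \code{description}, \code{kind} (\code{"quantitative"} or
#'   \code{"qualitative"}) and \code{encoding} (level coding for
#'   qualitative characters, \code{NA} otherwise).
#' @export
default_trait_schema <- function() {
  q <- function(code, desc) data.frame(code = code, description = desc,
                                       kind = "quantitative", encoding = NA_character_,
                                       stringsAsFactors = FALSE)
  ql <- function(code, desc, enc) data.frame(code = code, description = desc,
                                             kind = "qualitative", encoding = enc,
                                             stringsAsFactors = FALSE)
  schema <- rbind(
    q("AL",    "floret (anthecium) length"),
    q("AW",    "floret (anthecium) width"),
    q("DHC",   "dorsal hair length on callus"),
    q("VHC",   "ventral hair length on callus"),
    q("FL",    "callus foot ring length"),
    q("FW",    "callus foot ring width"),
    q("DHA",   "length of dorsal hairs on lemma"),
    q("VHA",   "length of ventral hairs on lemma"),
    q("CL",    "callus length"),
    q("CH",    "corolla hair length"),
    q("DDL",   "distance from end of dorsal hair line to top of lemma"),
    q("DVL",   "distance from end of ventral hair line to top of lemma"),
    q("Coll",  "column (lower awn segment) length"),
    q("CW",    "column width"),
    q("Seta",  "seta (upper awn segment) length"),
    q("Awn",   "awn length"),
    q("S/C",   "ratio of seta length to column length"),
    q("HC",    "length of hair on column"),
    q("HS",    "length of hair on seta"),
    q("HS/HC", "ratio of seta hair length to column hair length"),
    q("Culm",  "culm length"),
    q("LL",    "vegetative leaves length"),
    q("Lig",   "length of ligule of vegetative leaves"),
    q("UG",    "upper glume length"),
    q("LG",    "lower glume length"),
    q("LW",    "vegetative leaves width"),
    q("LAH",   "length of hairs on adaxial surface of vegetative leaf"),
    q("LLH",   "length of hairs on ligule of vegetative shoots"),
    q("USW",   "upper culm sheath width"),
    ql("NH",  "character of culm node",
       "glabrous=0, pilose=1"),
    ql("CS",  "character of culm sheaths",
       "glabrous=0, scabrous=1, pubescent=2"),
    ql("CAL", "character of abaxial surface of vegetative leaves",
       "glabrous=0, scabrous=1, shortly pilose=2"),
    ql("FR",  "character of callus foot ring",
       "pyriform=1, goblet-like concave=2, ovate=3"),
    ql("DS",  "character of dorsal surface of the callus",
       "glabrous=0, shortly pilose=1, pilose=2"),
    ql("USC", "character of upper culm sheath",
       "glabrous=0, scabrous=1, pubescent=2"))
  if (anyDuplicated(schema$code)) stop("schema codes must be unique")
  class(schema) <- c("trait_schema", "data.frame")
  schema
}

#' Construct a trait table
#'
#' Individuals x characters table of morphometric values, with group
#' labels and a schema describing each character.
#'
#' @param values numeric matrix or data frame, one row per individual,
#'   columns named by character code; quantitative characters numeric,
#'   qualitative characters integer-coded; \code{NA} allowed.
#' @param group_labels character vector, one group per individual.
#' @param schema a \code{trait_schema}; defaults to the bundled schema.
#' @param sample_ids optional sample identifiers.
#' @param strict if \code{TRUE} (default) a column absent from the schema
#'   is an error; otherwise it is dropped with a warning.
#' @return an object of class \code{trait_table}.
#' @export
trait_table <- function(values, group_labels, schema = default_trait_schema(),
                        sample_ids = rownames(values), strict = TRUE) {
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  unknown <- setdiff(colnames(values), schema$code)
  if (length(unknown)) {
    if (strict)
      stop("columns not in schema: ", paste(unknown, collapse = ", "))
    warning("dropping columns not in schema: ",
            paste(unknown, collapse = ", "))
    values <- values[, setdiff(colnames(values), unknown), drop = FALSE]
  }
  for (cc in colnames(values)) {
    kind <- schema$kind[schema$code == cc]
    v <- values[[cc]]
    if (!is.numeric(v))
      stop("non-numeric values in column ", cc)
    if (kind == "qualitative" && any(!is.na(v) & v != round(v)))
      stop("qualitative column ", cc, " must be integer-coded")
  }
  if (length(group_labels) != nrow(values))
    stop("group_labels must have one entry per individual")
  if (is.null(sample_ids)) sample_ids <- paste0("I", seq_len(nrow(values)))
  rownames(values) <- sample_ids
  structure(
    list(values = values, group_labels = as.character(group_labels),
         sample_ids = as.character(sample_ids), schema = schema),
    class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait_table: %d individuals x %d characters\n",
              nrow(x$values), ncol(x$values)))
  tb <- table(x$group_labels)
  cat("  groups:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
      "\n")
  invisible(x)
}
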