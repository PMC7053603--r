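#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join semi_join anti_join bind_rows distinct rename n
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map2 imap pmap map_dbl map_chr map_int map_lgl
#' @importFrom stats pt phyper p.adjust rnorm runif rbinom sd var cor t.test
#'   setNames
#' @importFrom utils head
NULL

# Input-validation helpers. All user-facing errors go through rlang::abort()
# with a class so callers (and tests) can match on them.

stop_input <- function(msg, class = "cernetr_input_error") {
  abort(msg, class = class)
}

stop_config <- function(msg) {
  abort(msg, class = "cernetr_config_error")
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) &&
    (if (strict_min) x > min else x >= min) && x <= max
  if (!ok) {
    stop_config(sprintf("invalid value for `%s`: must be a number in %s%s, %s]",
                        name, if (strict_min) "(" else "[",
                        format(min), format(max)))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && is.finite(x) &&
    x == round(x) && x >= min
  if (!ok) {
    stop_config(sprintf("invalid value for `%s`: must be an integer >= %d",
                        name, min))
  }
  invisible(as.integer(x))
}

check_prob <- function(x, name) {
  check_number(x, name, min = 0, max = 1)
}

# Derive a per-component RNG seed from a master seed so that independent
# stages draw from independent, reproducible streams. Kept below 2^31.
derive_seed <- function(seed, component) {
  stopifnot(is.character(component), length(component) == 1L)
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Expression tables are tibbles with a `feature_id` column followed by one
# numeric column per sample. These helpers convert to/from plain matrices.
expr_to_matrix <- function(expr) {
  if (!is.data.frame(expr) || !"feature_id" %in% names(expr)) {
    stop_input("expression table must be a data frame with a `feature_id` column")
  }
  m <- as.matrix(expr[setdiff(names(expr), "feature_id")])
  if (!is.numeric(m)) stop_input("expression values must be numeric")
  if (anyDuplicated(expr$feature_id)) {
    stop_input("duplicated feature_id values in expression table")
  }
  if (any(!is.finite(m))) stop_input("expression table contains non-finite values")
  rownames(m) <- expr$feature_id
  m
}

matrix_to_expr <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(feature_id = rownames(m)), out)
}

check_metadata <- function(metadata, sample_ids, design = c("paired", "group")) {
  design <- match.arg(design)
  req <- c("sample_id", "subject_id", "condition")
  if (!is.data.frame(metadata) || !all(req %in% names(metadata))) {
    stop_input("sample metadata must contain sample_id, subject_id and condition")
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop_input("duplicated sample_id values in metadata")
  }
  if (!all(metadata$condition %in% c("tumor", "normal"))) {
    stop_input("condition must be 'tumor' or 'normal'")
  }
  missing <- setdiff(sample_ids, metadata$sample_id)
  if (length(missing) > 0) {
    stop_input(sprintf("metadata missing samples present in the matrix: %s",
                       paste(missing, collapse = ", ")))
  }
  md <- metadata[match(sample_ids, metadata$sample_id), ]
  if (design == "paired") {
    tab <- table(md$subject_id, md$condition)
    if (!all(tab == 1L)) {
      stop_input("paired design requires exactly one tumor and one normal sample per subject")
    }
  }
  md
}
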