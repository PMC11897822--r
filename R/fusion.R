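# Fusion of reduced image features with clinical variables.
#
# Strategy 1 concatenates the reduced image features with encoded clinical
# variables: z = (ybar', v')'. Strategy 2 first embeds free-text clinical
# variables with a pluggable text embedder, reduces the embeddings with
# their own discriminant basis, then concatenates: z = (ybar', vbar')'.

#' Fit a clinical-variable encoder on training samples
#'
#' Numeric fields are z-scored with mean/sd estimated on the training rows
#' only; categorical fields are one-hot encoded with the category set frozen
#' at fit time (categories in order of first appearance). At transform time
#' an unknown category maps to all-zeros; a missing numeric value is imputed
#' with the training mean (i.e. 0 after z-scoring); a missing categorical
#' value maps to a dedicated "missing" category if missingness was seen at
#' fit time, else to all-zeros. Fields typed `"text"` are ignored by this
#' encoder (they belong to the embedding fusion strategy).
#'
#' @param table data.frame of per-sample clinical records (training rows).
#' @param schema named list/vector mapping column names to
#'   `"numeric"`, `"categorical"` or `"text"`.
#' @return an object of class `clinical_encoder`.
#' @seealso [encode_clinical()], [fuse_concat()]
#' @export
fit_clinical_encoder <- function(table, schema) {
  schema <- unlist(schema)
  bad <- setdiff(schema, c("numeric", "categorical", "text"))
  if (length(bad))
    stop_validation(paste("unknown schema types:", paste(bad, collapse = ", ")))
  miss <- setdiff(names(schema), names(table))
  if (length(miss))
    stop_validation(paste("clinical table is missing fields:",
                          paste(miss, collapse = ", ")))
  fields <- list()
  for (nm in names(schema)) {
    type <- schema[[nm]]
    if (type == "text") next
    col <- table[[nm]]
    if (type == "numeric") {
      col <- as.numeric(col)
      if (any(!is.finite(col) & !is.na(col)))
        stop_validation(sprintf("non-finite values in numeric field '%s'", nm))
      mu <- mean(col, na.rm = TRUE)
      sd_ <- stats::sd(col, na.rm = TRUE)
      if (!is.finite(sd_) || sd_ == 0) sd_ <- 1
      fields[[nm]] <- list(type = "numeric", mean = mu, sd = sd_)
    } else {
      chr <- as.character(col)
      levels <- unique(chr[!is.na(chr)])
      has_missing <- anyNA(chr)
      fields[[nm]] <- list(type = "categorical", levels = levels,
                           has_missing = has_missing)
    }
  }
  structure(list(fields = fields, schema = schema), class = "clinical_encoder")
}

#' Encode clinical records with a fitted encoder
#'
#' @param encoder a `clinical_encoder` from [fit_clinical_encoder()].
#' @param table data.frame of records to transform (any rows).
#' @return numeric matrix, one row per record, with descriptive column
#'   names; encoded width is fixed by the fitted encoder.
#' @export
encode_clinical <- function(encoder, table) {
  stopifnot(inherits(encoder, "clinical_encoder"))
  miss <- setdiff(names(encoder$fields), names(table))
  if (length(miss))
    stop_validation(paste("clinical table is missing fields:",
                          paste(miss, collapse = ", ")))
  blocks <- lapply(names(encoder$fields), function(nm) {
    f <- encoder$fields[[nm]]
    col <- table[[nm]]
    if (f$type == "numeric") {
      x <- as.numeric(col)
      if (any(!is.finite(x) & !is.na(x)))
        stop_validation(sprintf("non-finite values in numeric field '%s'", nm))
      x[is.na(x)] <- f$mean
      out <- matrix((x - f$mean) / f$sd, ncol = 1)
      colnames(out) <- nm
      out
    } else {
      chr <- as.character(col)
      levs <- f$levels
      width <- length(levs) + as.integer(f$has_missing)
      out <- matrix(0, nrow = length(chr), ncol = width)
      cn <- paste0(nm, "=", levs)
      if (f$has_missing) cn <- c(cn, paste0(nm, "=<missing>"))
      colnames(out) <- cn
      for (i in seq_along(chr)) {
        if (is.na(chr[i])) {
          if (f$has_missing) out[i, width] <- 1
        } else {
          j <- match(chr[i], levs)
          if (!is.na(j)) out[i, j] <- 1   # unknown category -> all zeros
        }
      }
      out
    }
  })
  if (!length(blocks)) return(matrix(0, nrow = nrow(table), ncol = 0))
  do.call(cbind, blocks)
}

new_fused <- function(vec_or_mat, L_img, L_cv) {
  parts <- list(image = seq_len(L_img),
                clinical = if (L_cv > 0) L_img + seq_len(L_cv) else integer(0))
  structure(list(vector = vec_or_mat, parts = parts), class = "fused_vector")
}

#' Concatenation fusion of reduced features and clinical variables
#'
#' Strategy 1: `z = (ybar', v')'`, image block first. The recorded block
#' boundaries allow exact recovery of both inputs. With an empty clinical
#' block the fused vector equals the reduced features (the "no clinical
#' variables" comparison arm).
#'
#' @param reduced length-L numeric vector (or N x L matrix) of reduced
#'   image features.
#' @param clinical encoded clinical vector of length `L_cv` (or N x L_cv
#'   matrix); may be zero-length/zero-column.
#' @return object of class `fused_vector` with elements `vector` (the
#'   concatenation, vector or matrix) and `parts` (index ranges of the
#'   image and clinical blocks).
#' @export
fuse_concat <- function(reduced, clinical = numeric(0)) {
  if (is.matrix(reduced) || is.matrix(clinical)) {
    reduced <- as.matrix(reduced)
    if (!is.matrix(clinical))
      clinical <- matrix(clinical, nrow = nrow(reduced),
                         ncol = length(clinical) / max(1, nrow(reduced)))
    if (nrow(clinical) != nrow(reduced) && ncol(clinical) > 0)
      stop_dimension("reduced and clinical must have the same number of rows")
    assert_finite(reduced, "reduced features")
    if (length(clinical)) assert_finite(clinical, "clinical block")
    z <- cbind(reduced, clinical)
    return(new_fused(z, ncol(reduced), ncol(clinical)))
  }
  reduced <- as.numeric(reduced)
  clinical <- as.numeric(clinical)
  assert_finite(reduced, "reduced features")
  if (length(clinical)) assert_finite(clinical, "clinical block")
  new_fused(c(reduced, clinical), length(reduced), length(clinical))
}

#' Embedding fusion of reduced features and clinical text
#'
#' Strategy 2: each sample's clinical text is embedded by a pluggable
#' deterministic embedder, reduced with a discriminant basis fitted on
#' training-fold embeddings, and concatenated after the image block:
#' `z = (ybar', vbar')'`.
#'
#' @param reduced length-L vector or N x L matrix of reduced image features.
#' @param clinical_text character vector of per-sample clinical text.
#' @param embedder function mapping one string to a fixed-length numeric
#'   vector (see [hash_embedder()]).
#' @param basis_cv [discriminant_basis] fitted on training-fold embeddings.
#' @return a `fused_vector` as in [fuse_concat()].
#' @export
fuse_embedded <- function(reduced, clinical_text, embedder, basis_cv) {
  stopifnot(is.function(embedder), inherits(basis_cv, "discriminant_basis"))
  emb <- t(vapply(clinical_text, function(txt) {
    v <- tryCatch(embedder(txt), error = function(e)
      fsda_stop(paste("embedder failed:", conditionMessage(e)),
                "fsdacam_embedding_error"))
    as.numeric(v)
  }, numeric(basis_cv$M)))
  vbar <- project(basis_cv, emb)
  if (is.matrix(reduced)) return(fuse_concat(reduced, vbar))
  if (length(clinical_text) != 1L)
    stop_dimension("vector `reduced` requires a single clinical text")
  fuse_concat(reduced, as.numeric(vbar))
}

#' Deterministic token-hashing text embedder
#'
#' A dependency-free stand-in for large language-model text embedders:
#' lower-cases, splits on non-alphanumerics, and accumulates each token into
#' a `dim`-length vector at a position (with sign) derived from a polynomial
#' rolling hash of the token. Identical text always yields an identical
#' embedding; no randomness is involved.
#'
#' @param dim embedding dimension (default 32).
#' @return a function `character(1) -> numeric(dim)`.
#' @examples
#' emb <- hash_embedder(16)
#' stopifnot(identical(emb("age 63 male"), emb("age 63 male")))
#' @export
hash_embedder <- function(dim = 32L) {
  dim <- as.integer(dim)
  if (dim < 1L) stop_validation("embedding dim must be >= 1")
  function(text) {
    v <- numeric(dim)
    tokens <- strsplit(tolower(as.character(text)), "[^a-z0-9]+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    for (tok in tokens) {
      h <- 0; h2 <- 0
      for (code in utf8ToInt(tok)) {
        h <- (h * 31 + code) %% 2147483647
        h2 <- (h2 * 37 + code * 7) %% 2147483647   # independent sign hash
      }
      idx <- ((h + h2) %% dim) + 1L
      sgn <- if (h2 %% 2 == 0) 1 else -1
      v[idx] <- v[idx] + sgn
    }
    v
  }
}

#' Read a clinical table and its schema
#'
#' The table is tab-delimited with a header; the schema is a YAML file
#' mapping column names to `numeric`, `categorical` or `text`.
#'
#' @param path clinical table path (TSV).
#' @param schema_path YAML schema path.
#' @return list with `table` (data.frame) and `schema` (named list).
#' @export
read_clinical <- function(path, schema_path) {
  table <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  schema <- yaml::read_yaml(schema_path)
  list(table = table, schema = schema)
}

#' @rdname read_clinical
#' @param table data.frame to write.
#' @param schema named list to write.
#' @export
write_clinical <- function(table, schema, path, schema_path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(schema, schema_path)
  invisible(path)
}
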