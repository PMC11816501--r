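# Internal helpers: seeded streams, canonical serialization, apportionment.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a purpose-specific seed from a root seed
#'
#' Every stochastic stage of the package (case generation, predicted-negative
#' selection, mutation, reviewer assignment) draws from its own stream derived
#' from one root seed, so that adding cases to one stage never reshuffles the
#' randomness of another.
#'
#' @param root_seed integer root seed.
#' @param purpose short string naming the stream (e.g. `"casegen"`).
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(root_seed, purpose) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.character(purpose))
  h <- abs(root_seed) %% 2147483647
  for (b in utf8ToInt(enc2utf8(purpose))) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h)
}

with_stream <- function(root_seed, purpose, code) {
  withr::with_seed(derive_seed(root_seed, purpose), code)
}

# Canonical JSON used for prediction digests and byte-level determinism checks.
canonical_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, null = "null"))
}

# 32-bit FNV-1a over a UTF-8 string; returned as 8 hex characters.
# Used for compact baseline digests (full canonical JSON comparison is used
# wherever an equality decision matters).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- (h - low) + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# Largest-remainder apportionment of `total` units over non-negative weights.
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), sum(weights) > 0, total >= 0)
  exact <- weights / sum(weights) * total
  base <- floor(exact)
  k <- as.integer(round(total - sum(base)))
  if (k > 0) {
    idx <- order(exact - base, decreasing = TRUE)[seq_len(k)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# Issue tables shared by record and knowledge-base validation.
issue_table <- function() {
  data.frame(field = character(), kind = character(), message = character(),
             stringsAsFactors = FALSE)
}

add_issue <- function(issues, field, kind, message) {
  rbind(issues, data.frame(field = field, kind = kind, message = message,
                           stringsAsFactors = FALSE))
}

config_error <- function(message) {
  stop(structure(class = c("cdsrules_config_error", "error", "condition"),
                 list(message = message, call = NULL)))
}
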