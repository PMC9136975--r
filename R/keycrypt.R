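#' Serialize a digitized key to bytes for hashing
#'
#' The bits are rendered as ASCII '0'/'1' characters preceded by the
#' header `n=<n>;order=ECFP,EGFP,MKATE2;`. The convention is unambiguous
#' and padding-free, and accepts raw (possibly exclusivity-violating)
#' decoder output so that any decoded key can be hashed.
#'
#' @param key a `digitized_key`.
#' @return Raw byte vector.
#' @export
serialize_key <- function(key) {
  stopifnot(inherits(key, "digitized_key"))
  charToRaw(paste0("n=", key$n, ";order=",
                   paste(key$channel_order, collapse = ","), ";",
                   paste(key$bits, collapse = "")))
}

#' Parse the byte serialization back into a digitized key
#'
#' @param bytes raw vector produced by [serialize_key()].
#' @return A `digitized_key`.
#' @export
deserialize_key <- function(bytes) {
  s <- rawToChar(bytes)
  m <- regmatches(s, regexec("^n=([0-9]+);order=([A-Z0-9,]+);([01]+)$", s))[[1]]
  if (length(m) != 4) stop("not a valid key serialization")
  if (m[3] != paste(channel_order, collapse = ","))
    stop("unexpected channel order: ", m[3])
  digitized_key(as.integer(strsplit(m[4], "")[[1]]), n = as.integer(m[2]))
}

.hash_algorithms <- c(md5 = 128L, sha256 = 256L, sha512 = 512L)

#' Hash a digitized key into a fixed-length digest
#'
#' The extracted digitized key is fed through a one-way cryptographic
#' hash, yielding the hashed key used for registry authentication. MD5
#' produces a 128-bit hashed key; SHA-256 and SHA-512 are stronger
#' alternatives. MD5 is retained for interoperability but is
#' cryptographically broken; prefer SHA-256 for new registries.
#'
#' @param key a `digitized_key` (validity not required).
#' @param algorithm one of `"md5"`, `"sha256"`, `"sha512"`.
#' @return A `hashed_key`: list with `algorithm`, lowercase hex `digest`,
#'   `bit_length`, and `source_serialization` label.
#' @export
hash_key <- function(key, algorithm = c("sha256", "md5", "sha512")) {
  algorithm <- match.arg(algorithm)
  bytes <- serialize_key(key)
  digest <- switch(algorithm,
    md5    = openssl::md5(bytes),
    sha256 = openssl::sha256(bytes),
    sha512 = openssl::sha512(bytes))
  structure(list(algorithm = algorithm,
                 digest = tolower(paste(unclass(as.character(digest)))),
                 bit_length = .hash_algorithms[[algorithm]],
                 source_serialization = "ascii-bits-v1"),
            class = "hashed_key")
}

#' @export
print.hashed_key <- function(x, ...) {
  cat(toupper(x$algorithm), " hashed key (", x$bit_length, " bits): ",
      x$digest, "\n", sep = "")
  invisible(x)
}

#' Create an empty key registry
#'
#' A registry maps hashed-key digests to product records (dosage
#' strength, dose frequency, expiration date, manufacturing details and
#' so on) and is the authentication surface scanned codes are checked
#' against. All digests in one registry use the same algorithm.
#'
#' @param algorithm hash algorithm tag for every entry.
#' @return A `key_registry`.
#' @export
key_registry <- function(algorithm = c("sha256", "md5", "sha512")) {
  structure(list(algorithm = match.arg(algorithm),
                 entries = structure(list(), names = character(0))),
            class = "key_registry")
}

#' Register a hashed key with its product record
#'
#' @param registry a `key_registry`.
#' @param hashed a `hashed_key` (or a `digitized_key`, hashed with the
#'   registry's algorithm).
#' @param record named list of product information.
#' @param overwrite replace an existing entry instead of erroring.
#' @return The updated registry.
#' @export
register_key <- function(registry, hashed, record, overwrite = FALSE) {
  stopifnot(inherits(registry, "key_registry"))
  if (inherits(hashed, "digitized_key"))
    hashed <- hash_key(hashed, registry$algorithm)
  stopifnot(inherits(hashed, "hashed_key"))
  if (hashed$algorithm != registry$algorithm)
    stop("registry uses ", registry$algorithm, " but key was hashed with ",
         hashed$algorithm)
  if (!overwrite && hashed$digest %in% names(registry$entries))
    stop("digest already registered (pass overwrite = TRUE to replace)")
  registry$entries[[hashed$digest]] <- record
  registry
}

#' Authenticate a key (or digest) against a registry
#'
#' Matching is exact digest equality only; a near-miss (for instance a
#' single flipped key bit) is simply "not authentic". Unknown digests are
#' a valid negative outcome, not an error.
#'
#' @param registry a `key_registry`.
#' @param key a `digitized_key`, `hashed_key`, or hex digest string.
#' @return List with `authentic` (logical) and `record` (the stored
#'   product record, or `NULL`).
#' @export
verify_key <- function(registry, key) {
  stopifnot(inherits(registry, "key_registry"))
  digest <- if (inherits(key, "digitized_key")) {
    hash_key(key, registry$algorithm)$digest
  } else if (inherits(key, "hashed_key")) {
    key$digest
  } else {
    tolower(as.character(key))
  }
  hit <- digest %in% names(registry$entries)
  list(authentic = hit,
       record = if (hit) registry$entries[[digest]] else NULL)
}

#' Save a registry to a JSON file
#'
#' @param registry a `key_registry`.
#' @param path output file.
#' @export
save_registry <- function(registry, path) {
  jsonlite::write_json(list(algorithm = registry$algorithm,
                            entries = registry$entries),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a registry from a JSON file
#'
#' @param path JSON file written by [save_registry()].
#' @return A `key_registry`.
#' @export
load_registry <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  reg <- key_registry(obj$algorithm)
  reg$entries <- obj$entries
  if (is.null(names(reg$entries))) names(reg$entries) <- character(0)
  reg
}
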