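#' @keywords internal
"_PACKAGE"

# 32-bit FNV-1a over a byte vector, carried as two 16-bit halves so that the
# multiply never leaves the exact-integer range of a double.
fnv1a32 <- function(bytes) {
  hi <- 33052L   # 0x811C
  lo <- 40389L   # 0x9DC5
  prime <- 16777619
  for (b in bytes) {
    lo <- bitwXor(lo, as.integer(b))
    t <- lo * prime
    new_lo <- t %% 65536
    carry <- (t - new_lo) / 65536
    hi <- (hi * prime + carry) %% 65536
    lo <- new_lo
  }
  hi * 65536 + lo
}

#' Derive a reproducible substream seed
#'
#' Maps a master seed plus a stage label and index to an integer seed by
#' hashing the triple. Different labels or indices give unrelated streams, so
#' per-replicate draws can be re-created in isolation without replaying the
#' whole run.
#'
#' @param master_seed Integer master seed of the run.
#' @param label Character stage label (e.g. `"replicate"`, `"genotypes"`).
#' @param index Integer index within the stage (default 0).
#' @return A single integer in `[0, 2^31 - 1]`, suitable for [set.seed()].
#' @examples
#' derive_substream(42, "replicate", 1)
#' @export
derive_substream <- function(master_seed, label, index = 0L) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(label), length(label) == 1L)
  key <- paste(format(master_seed, scientific = FALSE), label,
               format(index, scientific = FALSE), sep = "\x1f")
  as.integer(fnv1a32(utf8ToInt(key)) %% 2147483647)
}

# md5 of an arbitrary R object via its serialized bytes (version 2 for
# stability across sessions).
object_digest <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(x, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
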