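#' Paired IP/supernatant intensity container
#'
#' Holds the two channel matrices of an epitranscriptomic array experiment
#' (linear-scale intensities, transcript probes x samples), the sample sheet,
#' and the spike-in registry. Both matrices must share row and column
#' orderings; intensities are floored at load time so that log2 is defined.
#'
#' @param ip,sup numeric matrices (probes x samples) for the
#'   immunoprecipitated (Cy5) and supernatant (Cy3) channels.
#' @param samples sample sheet data frame with columns `sample_id`, `group`,
#'   `replicate`.
#' @param spikein_ids probe ids of the spike-in controls (non-empty).
#' @param annotation optional probe annotation data frame carried along for
#'   downstream stages.
#' @param floor intensity floor applied to both channels.
#' @return list of class `two_channel_set`.
#' @export
two_channel_set <- function(ip, sup, samples, spikein_ids, annotation = NULL,
                            floor = 1) {
  ip <- as.matrix(ip); sup <- as.matrix(sup)
  if (!identical(dim(ip), dim(sup)) ||
      !identical(rownames(ip), rownames(sup)) ||
      !identical(colnames(ip), colnames(sup)))
    stopf("ip and sup matrices must share dimensions and dimnames")
  if (is.null(rownames(ip)) || is.null(colnames(ip)))
    stopf("intensity matrices need probe rownames and sample colnames")
  dup <- rownames(ip)[duplicated(rownames(ip))]
  if (length(dup)) stopf("duplicated probe id: %s", dup[1])
  need <- c("sample_id", "group", "replicate")
  if (!all(need %in% names(samples))) stopf("sample sheet needs columns %s",
                                            paste(need, collapse = ", "))
  missing <- setdiff(colnames(ip), samples$sample_id)
  if (length(missing))
    stopf("sample present in matrix but absent from sheet: %s", missing[1])
  samples <- samples[match(colnames(ip), samples$sample_id), , drop = FALSE]
  if (length(spikein_ids) == 0) stopf("spike-in set must be non-empty")
  if (!all(spikein_ids %in% rownames(ip)))
    stopf("spike-in ids missing from intensity matrices")
  n_floored <- sum(ip < floor) + sum(sup < floor)
  if (n_floored > 0)
    message(n_floored, " intensities floored to ", floor)
  ip[ip < floor] <- floor
  sup[sup < floor] <- floor
  structure(list(ip = ip, sup = sup, samples = samples,
                 spikein_ids = as.character(spikein_ids),
                 annotation = annotation, floor = floor,
                 n_floored = n_floored),
            class = "two_channel_set")
}

#' @export
print.two_channel_set <- function(x, ...) {
  cat("two_channel_set:", nrow(x$ip), "probes x", ncol(x$ip), "samples;",
      length(x$spikein_ids), "spike-ins;",
      length(unique(x$samples$group)), "groups\n")
  invisible(x)
}

#' Spike-in control normalization
#'
#' For each sample s and channel c, the normalization factor is the mean
#' log2 intensity of the spike-in controls, `f(s, c)`. Normalized log2
#' intensity is `raw log2 - f(s, c) + F`, where `F` is the grand mean of all
#' `f(s, c)`. Recentring by `F` (instead of to zero) keeps normalized values
#' on an intensity-like scale; after normalization the per-array spike-in
#' mean log2 equals `F` for every sample and channel.
#'
#' @param x a [two_channel_set()].
#' @return list with `norm_ip`, `norm_sup` (linear-scale normalized
#'   matrices) and `factors` (data frame: sample_id, channel,
#'   mean_log2_spikein, offset).
#' @export
spikein_normalize <- function(x) {
  stopifnot(inherits(x, "two_channel_set"))
  spike <- x$spikein_ids
  lip <- log2(x$ip); lsup <- log2(x$sup)
  f_ip <- colMeans(lip[spike, , drop = FALSE])
  f_sup <- colMeans(lsup[spike, , drop = FALSE])
  fbar <- mean(c(f_ip, f_sup))
  norm_ip <- 2^sweep(lip, 2, f_ip - fbar)
  norm_sup <- 2^sweep(lsup, 2, f_sup - fbar)
  factors <- data.frame(
    sample_id = rep(colnames(x$ip), 2),
    channel = rep(c("IP", "SUP"), each = ncol(x$ip)),
    mean_log2_spikein = c(f_ip, f_sup),
    offset = c(fbar - f_ip, fbar - f_sup), row.names = NULL)
  list(norm_ip = norm_ip, norm_sup = norm_sup, factors = factors,
       grand_mean = fbar)
}

#' Percent modification
#'
#' Per-transcript m6A methylation level: `100 * ip / (ip + sup)` on
#' normalized linear intensities. Entries where both channels are zero are
#' defined as 0 and counted in the `n_zero` attribute.
#'
#' @param norm_ip,norm_sup aligned normalized intensity matrices (values
#'   >= 0).
#' @return matrix of percent modification in \[0, 100\].
#' @export
percent_modification <- function(norm_ip, norm_sup) {
  if (!identical(dim(norm_ip), dim(norm_sup)))
    stopf("percent_modification: shape mismatch")
  denom <- norm_ip + norm_sup
  zero <- denom == 0
  denom[zero] <- 1
  m <- 100 * norm_ip / denom
  m[zero] <- 0
  attr(m, "n_zero") <- sum(zero)
  m
}

#' Expression level
#'
#' Default mode `"total"` takes the channel sum (modified + unmodified RNA);
#' mode `"supernatant"` takes the Cy3 channel alone.
#'
#' @param norm_ip,norm_sup aligned normalized intensity matrices.
#' @param mode `"total"` or `"supernatant"`.
#' @return expression matrix with attribute `mode`.
#' @export
expression_level <- function(norm_ip, norm_sup,
                             mode = c("total", "supernatant")) {
  mode <- match.arg(mode)
  if (!identical(dim(norm_ip), dim(norm_sup)))
    stopf("expression_level: shape mismatch")
  e <- if (mode == "total") norm_ip + norm_sup else norm_sup
  attr(e, "mode") <- mode
  e
}

#' Quantify a two-channel array set
#'
#' Runs spike-in normalization, percent modification and expression in one
#' step.
#'
#' @param x a [two_channel_set()].
#' @param expression_mode passed to [expression_level()].
#' @return list of class `quantified_set` with elements `norm_ip`,
#'   `norm_sup`, `methylation` (percent), `expression`, `factors`,
#'   `samples`, `spikein_ids`, `annotation`, `expression_mode`.
#' @export
quantify <- function(x, expression_mode = "total") {
  nm <- spikein_normalize(x)
  structure(list(
    norm_ip = nm$norm_ip, norm_sup = nm$norm_sup,
    methylation = percent_modification(nm$norm_ip, nm$norm_sup),
    expression = expression_level(nm$norm_ip, nm$norm_sup, expression_mode),
    factors = nm$factors, samples = x$samples, spikein_ids = x$spikein_ids,
    annotation = x$annotation, expression_mode = expression_mode),
    class = "quantified_set")
}
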