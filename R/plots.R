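# ggplot2 figure analogues: volcano plot, distance densities, motif
# frequency profiles, phenotype heatmap.

#' Volcano plot of differential splicing
#'
#' Delta PSI against -log10 FDR, coloured by significance at the
#' |delta PSI| >= 0.1 preset.
#'
#' @param object A `splice_diff` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.splice_diff <- function(object, ...) {
  df <- as_tibble(object) %>% filter(.data$testable)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$delta_psi,
    y = -log10(pmax(.data$fdr, 1e-300)),
    colour = .data$significant_010)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = "significant") +
    ggplot2::labs(x = expression(Delta * PSI), y = expression(-log[10](FDR))) +
    ggplot2::theme_minimal()
}

#' Distance density plots for one or more signatures
#'
#' Kernel-density analogue of the cryptic-to-canonical acceptor distance
#' figures: either the absolute distance |d| or the signed relative
#' position d (negative = upstream of the canonical AG).
#'
#' @param signatures Named list of `"a3ss_signature"` objects (or distance
#'   tibbles from [signed_distance()]).
#' @param type `"absolute"` or `"signed"`.
#' @return A ggplot.
#' @export
plot_distance_density <- function(signatures, type = c("absolute", "signed")) {
  type <- match.arg(type)
  if (inherits(signatures, "a3ss_signature")) {
    signatures <- list(signature = signatures)
  }
  df <- purrr::imap_dfr(signatures, function(s, nm) {
    d <- if (inherits(s, "a3ss_signature")) s$distances else s
    mutate(d, condition = nm)
  })
  x <- if (type == "absolute") "abs_d" else "d"
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]],
                                   colour = .data$condition,
                                   fill = .data$condition)) +
    ggplot2::geom_density(alpha = 0.2, adjust = 1.5) +
    ggplot2::labs(
      x = if (type == "absolute")
        "|distance| cryptic AG' to canonical AG (nt)"
      else "relative position of cryptic AG' (nt)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_distance_density
#' @param object An `"a3ss_signature"`.
#' @param ... Passed to [plot_distance_density()].
#' @export
autoplot.a3ss_signature <- function(object, ...) {
  plot_distance_density(list(signature = object), ...)
}

#' Motif frequency profile plot
#'
#' Per-position nucleotide frequencies of an acceptor motif matrix,
#' anchored on the AG dinucleotide.
#'
#' @param object A `"motif_matrix"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.motif_matrix <- function(object, ...) {
  m <- object$freq
  df <- as_tibble(m, rownames = "base") %>%
    tidyr::pivot_longer(-"base", names_to = "position",
                        values_to = "frequency") %>%
    mutate(position = factor(.data$position, levels = colnames(m)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$frequency,
                                   colour = .data$base,
                                   group = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_discrete(breaks = c("-50", "-40", "-30", "-20", "-10",
                                         "-1", "A", "G", "+3")) +
    ggplot2::labs(x = "position relative to acceptor AG",
                  y = "frequency") +
    ggplot2::theme_minimal()
}

#' Phenotype heatmap with dendrogram ordering
#'
#' Patients (columns) in dendrogram order, features (rows); missing values
#' shown in grey, severity on the white-to-blue 0 / 0.5 / 1 scale.
#'
#' @param object A `"pheno_cluster"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pheno_cluster <- function(object, ...) {
  df <- object$data %>%
    dplyr::select(-dplyr::any_of("variant")) %>%
    tidyr::pivot_longer(-"patient", names_to = "feature",
                        values_to = "value") %>%
    mutate(patient = factor(.data$patient, levels = object$order))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$patient, y = .data$feature,
                                   fill = .data$value)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue4",
                                 limits = c(0, 1), na.value = "grey70",
                                 name = "severity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
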