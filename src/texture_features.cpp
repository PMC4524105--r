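#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 18 Haralick-style statistics from a symmetric, normalized GLCM.
// Levels are 1..L; entropies in bits. Layout of out[0..17] follows the
// feature inventory: energy, contrast, correlation, variance, inverse
// difference moment, sum average, sum variance, sum entropy, entropy,
// difference variance, difference entropy, information measure of
// correlation (IMC1), homogeneity, autocorrelation, dissimilarity,
// cluster shade, cluster prominence, maximum probability.
static void glcmStats(const std::vector<double>& p, int L, double* out) {
    const double log2e = 1.0 / std::log(2.0);
    std::vector<double> px(L, 0.0), psum(2 * L + 1, 0.0), pdiff(L, 0.0);
    double energy = 0, entropy = 0, contrast = 0, dissim = 0, homog = 0,
           idm = 0, autoc = 0, maxp = 0, cross = 0;
    for (int j = 0; j < L; ++j) {
        for (int i = 0; i < L; ++i) {
            double pij = p[i + L * j];
            if (pij <= 0.0) continue;
            double vi = i + 1, vj = j + 1, dd = vi - vj, ad = std::fabs(dd);
            px[i] += pij;
            psum[(int)(vi + vj)] += pij;
            pdiff[(int)ad] += pij;
            energy += pij * pij;
            entropy -= pij * std::log(pij) * log2e;
            contrast += dd * dd * pij;
            dissim += ad * pij;
            homog += pij / (1.0 + ad);
            idm += pij / (1.0 + dd * dd);
            autoc += vi * vj * pij;
            cross += vi * vj * pij;
            if (pij > maxp) maxp = pij;
        }
    }
    double mu = 0, sig2 = 0, hx = 0;
    for (int i = 0; i < L; ++i) mu += (i + 1) * px[i];
    for (int i = 0; i < L; ++i) {
        double d = (i + 1) - mu;
        sig2 += d * d * px[i];
        if (px[i] > 0) hx -= px[i] * std::log(px[i]) * log2e;
    }
    double corr = (sig2 > 1e-12) ? (cross - mu * mu) / sig2 : 0.0;
    // variance: spread of levels about the GLCM mean (equals sig2 for a
    // symmetric matrix); cluster shade/prominence about 2*mu
    double shade = 0, prom = 0;
    for (int j = 0; j < L; ++j)
        for (int i = 0; i < L; ++i) {
            double pij = p[i + L * j];
            if (pij <= 0.0) continue;
            double s = (i + 1) + (j + 1) - 2.0 * mu;
            shade += s * s * s * pij;
            prom += s * s * s * s * pij;
        }
    double sumavg = 0, sument = 0;
    for (int k = 2; k <= 2 * L; ++k) {
        if (psum[k] <= 0) continue;
        sumavg += k * psum[k];
        sument -= psum[k] * std::log(psum[k]) * log2e;
    }
    double sumvar = 0;
    for (int k = 2; k <= 2 * L; ++k) {
        if (psum[k] <= 0) continue;
        double d = k - sumavg;
        sumvar += d * d * psum[k];
    }
    double diffavg = 0, diffent = 0;
    for (int k = 0; k < L; ++k) {
        if (pdiff[k] <= 0) continue;
        diffavg += k * pdiff[k];
        diffent -= pdiff[k] * std::log(pdiff[k]) * log2e;
    }
    double diffvar = 0;
    for (int k = 0; k < L; ++k) {
        if (pdiff[k] <= 0) continue;
        double d = k - diffavg;
        diffvar += d * d * pdiff[k];
    }
    // IMC1: (HXY - HXY1) / max(HX, HY); symmetric GLCM so HY = HX
    double hxy1 = 0;
    for (int j = 0; j < L; ++j)
        for (int i = 0; i < L; ++i) {
            double pij = p[i + L * j];
            if (pij <= 0.0 || px[i] <= 0.0 || px[j] <= 0.0) continue;
            hxy1 -= pij * std::log(px[i] * px[j]) * log2e;
        }
    double imc1 = (hx > 1e-12) ? (entropy - hxy1) / hx : 0.0;

    out[0] = energy;  out[1] = contrast; out[2] = corr;   out[3] = sig2;
    out[4] = idm;     out[5] = sumavg;   out[6] = sumvar; out[7] = sument;
    out[8] = entropy; out[9] = diffvar;  out[10] = diffent; out[11] = imc1;
    out[12] = homog;  out[13] = autoc;   out[14] = dissim;
    out[15] = shade;  out[16] = prom;    out[17] = maxp;
}

// Accumulate the symmetric normalized GLCM of a sub-window of `quant`
// (1-based clipped bounds) for offset (dr, dc); returns false if no pairs.
static bool buildGlcm(const IntegerMatrix& quant, int r0, int r1, int c0,
                      int c1, int dr, int dc, int L, std::vector<double>& p) {
    std::fill(p.begin(), p.end(), 0.0);
    double total = 0.0;
    for (int c = c0; c <= c1; ++c) {
        for (int r = r0; r <= r1; ++r) {
            int rr = r + dr, cc = c + dc;
            if (rr < r0 || rr > r1 || cc < c0 || cc > c1) continue;
            int a = quant(r, c) - 1, b = quant(rr, cc) - 1;
            p[a + L * b] += 1.0;
            p[b + L * a] += 1.0;
            total += 2.0;
        }
    }
    if (total <= 0.0) return false;
    for (size_t k = 0; k < p.size(); ++k) p[k] /= total;
    return true;
}

// GLCM offsets (dr, dc) for 0, 45, 90, 135 degrees at distance 1, with
// matrix rows increasing downwards (image convention).
static const int DIR_DR[4] = {0, -1, -1, -1};
static const int DIR_DC[4] = {1, 1, 0, -1};

// [[Rcpp::export]]
NumericVector cppGlcmStats(IntegerMatrix patch, int levels, int direction) {
    if (direction < 0 || direction > 3) stop("direction must be 0..3");
    std::vector<double> p(levels * levels);
    NumericVector out(18);
    bool ok = buildGlcm(patch, 0, patch.nrow() - 1, 0, patch.ncol() - 1,
                        DIR_DR[direction], DIR_DC[direction], levels, p);
    if (!ok) return out;  // no co-occurring pairs: all stats 0
    glcmStats(p, levels, REAL(out));
    return out;
}

// Sliding first-order (4) + GLCM (18 x 4 directions) features for a set
// of window centres on one slice. `raw` supplies intensities for the
// first-order statistics, `quant` the 1..levels quantized image for the
// GLCMs. Windows are clipped at the slice border. Centres are 1-based.
// [[Rcpp::export]]
NumericMatrix cppSlidingTexture(NumericMatrix raw, IntegerMatrix quant,
                                IntegerVector rows, IntegerVector cols,
                                int half, int levels) {
    int n = rows.size(), nr = raw.nrow(), nc = raw.ncol();
    NumericMatrix out(n, 76);
    std::vector<double> p(levels * levels);
    double stats[18];
    for (int s = 0; s < n; ++s) {
        int r = rows[s] - 1, c = cols[s] - 1;
        int r0 = std::max(0, r - half), r1 = std::min(nr - 1, r + half);
        int c0 = std::max(0, c - half), c1 = std::min(nc - 1, c + half);
        // first-order moments of the raw window
        double m1 = 0, m2 = 0, m3 = 0, m4 = 0;
        int cnt = (r1 - r0 + 1) * (c1 - c0 + 1);
        for (int cc = c0; cc <= c1; ++cc)
            for (int rr = r0; rr <= r1; ++rr) m1 += raw(rr, cc);
        m1 /= cnt;
        for (int cc = c0; cc <= c1; ++cc)
            for (int rr = r0; rr <= r1; ++rr) {
                double d = raw(rr, cc) - m1, d2 = d * d;
                m2 += d2; m3 += d2 * d; m4 += d2 * d2;
            }
        m2 /= cnt; m3 /= cnt; m4 /= cnt;
        out(s, 0) = m1;
        out(s, 1) = std::sqrt(m2);
        // degenerate (constant) windows: skewness and excess kurtosis 0
        out(s, 2) = (m2 > 1e-24) ? m3 / std::pow(m2, 1.5) : 0.0;
        out(s, 3) = (m2 > 1e-24) ? m4 / (m2 * m2) - 3.0 : 0.0;
        for (int d = 0; d < 4; ++d) {
            bool ok = buildGlcm(quant, r0, r1, c0, c1, DIR_DR[d], DIR_DC[d],
                                levels, p);
            if (ok) {
                glcmStats(p, levels, stats);
                for (int k = 0; k < 18; ++k) out(s, 4 + 18 * d + k) = stats[k];
            }
        }
    }
    return out;
}
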