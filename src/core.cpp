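#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// coords layout: array dim (n2, 3, M); element (i, d, m) at i + n2*d + 3*n2*m.
static inline double dist2(const double* x, int n2, int m, int i, int j) {
    const double* a = x + (std::size_t)3 * n2 * m;
    double s = 0.0;
    for (int d = 0; d < 3; ++d) {
        double v = a[i + n2 * d] - a[j + n2 * d];
        s += v * v;
    }
    return s;
}

// Haploid contact frequencies from a diploid structure population.
// chrom: per haploid bin chromosome id (int), N bins; beads: copy0 = bin,
// copy1 = bin + N (0-based).  cis pairs count the 2 within-homolog
// combinations, trans pairs all 4; both are divided by 2M and clipped to 1.
// [[Rcpp::export(name = ".cppContactFrequencies")]]
NumericMatrix cppContactFrequencies(NumericVector coords, IntegerVector chrom,
                                    double cutoff) {
    IntegerVector dims = coords.attr("dim");
    int n2 = dims[0], M = dims[2], N = n2 / 2;
    const double* x = coords.begin();
    double c2 = cutoff * cutoff;
    NumericMatrix F(N, N);
    for (int m = 0; m < M; ++m) {
        for (int I = 0; I < N; ++I) {
            for (int J = I + 1; J < N; ++J) {
                int cnt = 0;
                if (chrom[I] == chrom[J]) {
                    // cis: the two within-homolog combinations, each
                    // contributing 1/(2M)
                    if (dist2(x, n2, m, I, J) <= c2) ++cnt;
                    if (dist2(x, n2, m, I + N, J + N) <= c2) ++cnt;
                } else {
                    // trans: a structure is in contact when any of the four
                    // copy combinations is (contributes 1/M), mirroring the
                    // one-combination-per-structure contact assignment
                    if (dist2(x, n2, m, I, J) <= c2 ||
                        dist2(x, n2, m, I, J + N) <= c2 ||
                        dist2(x, n2, m, I + N, J) <= c2 ||
                        dist2(x, n2, m, I + N, J + N) <= c2) cnt = 2;
                }
                F(I, J) += cnt;
            }
        }
    }
    double denom = 2.0 * M;
    for (int I = 0; I < N; ++I)
        for (int J = I + 1; J < N; ++J) {
            double f = F(I, J) / denom;
            if (f > 1.0) f = 1.0;
            F(I, J) = f;
            F(J, I) = f;
        }
    return F;
}

// For each haploid pair (row of `pairs`, 0-based I, J) and each structure,
// the minimal copy-combination distance and the arg-min combination.
// Combos are indexed 0..3 as (i,j), (i,j'), (i',j), (i',j'); cis pairs only
// use combos 0 and 3.
// [[Rcpp::export(name = ".cppMinComboDistance")]]
List cppMinComboDistance(NumericVector coords, IntegerMatrix pairs,
                         LogicalVector isCis) {
    IntegerVector dims = coords.attr("dim");
    int n2 = dims[0], M = dims[2], N = n2 / 2;
    const double* x = coords.begin();
    int np = pairs.nrow();
    NumericMatrix dmin(np, M);
    IntegerMatrix combo(np, M);
    for (int p = 0; p < np; ++p) {
        int I = pairs(p, 0), J = pairs(p, 1);
        bool cis = isCis[p];
        for (int m = 0; m < M; ++m) {
            double best = dist2(x, n2, m, I, J);
            int bc = 0;
            double d3 = dist2(x, n2, m, I + N, J + N);
            if (d3 < best) { best = d3; bc = 3; }
            if (!cis) {
                double d1 = dist2(x, n2, m, I, J + N);
                if (d1 < best) { best = d1; bc = 1; }
                double d2 = dist2(x, n2, m, I + N, J);
                if (d2 < best) { best = d2; bc = 2; }
            }
            dmin(p, m) = std::sqrt(best);
            combo(p, m) = bc;
        }
    }
    return List::create(_["dmin"] = dmin, _["combo"] = combo);
}

struct PenaltyStats {
    double penalty;
    int nViol;
    int nRestraints;
};

// One-sided harmonic penalty (sum of squared excesses, nm^2) and the count of
// restraints whose relative excess exceeds relTol.
static PenaltyStats structurePenalty(const double* x, int n2, int m,
                                     const IntegerMatrix& chain, double Dchain,
                                     const std::vector<int>& cFrom,
                                     const IntegerMatrix& contacts,
                                     double Dcontact, double Rex, double Rnuc,
                                     double relTol) {
    PenaltyStats st = {0.0, 0, 0};
    double hard = 2.0 * Rex;
    // chain
    for (int k = 0; k < chain.nrow(); ++k) {
        double d = std::sqrt(dist2(x, n2, m, chain(k, 0), chain(k, 1)));
        ++st.nRestraints;
        if (d > Dchain) {
            double e = d - Dchain;
            st.penalty += e * e;
            if (e / Dchain > relTol) ++st.nViol;
        }
    }
    // contacts of this structure (rows cFrom[m] .. cFrom[m+1]-1)
    for (int k = cFrom[m]; k < cFrom[m + 1]; ++k) {
        double d = std::sqrt(dist2(x, n2, m, contacts(k, 1), contacts(k, 2)));
        ++st.nRestraints;
        if (d > Dcontact) {
            double e = d - Dcontact;
            st.penalty += e * e;
            if (e / Dcontact > relTol) ++st.nViol;
        }
    }
    // excluded volume, all bead pairs
    double hard2 = hard * hard;
    for (int i = 0; i < n2; ++i) {
        for (int j = i + 1; j < n2; ++j) {
            double d2 = dist2(x, n2, m, i, j);
            if (d2 < hard2) {
                double d = std::sqrt(d2);
                double e = hard - d;
                st.penalty += e * e;
                ++st.nRestraints;
                if (e / hard > relTol) ++st.nViol;
            }
        }
    }
    // envelope
    const double* a = x + (std::size_t)3 * n2 * m;
    for (int i = 0; i < n2; ++i) {
        double r = std::sqrt(a[i] * a[i] + a[i + n2] * a[i + n2] +
                             a[i + 2 * n2] * a[i + 2 * n2]);
        ++st.nRestraints;
        if (r > Rnuc) {
            double e = r - Rnuc;
            st.penalty += e * e;
            if (e / Rnuc > relTol) ++st.nViol;
        }
    }
    return st;
}

static inline void projectPair(double* a, int n2, int i, int j, double target,
                               bool upper, std::mt19937& rng) {
    double dx = a[j] - a[i], dy = a[j + n2] - a[i + n2],
           dz = a[j + 2 * n2] - a[i + 2 * n2];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (upper) {
        if (d <= target) return;
    } else {
        if (d >= target) return;
    }
    double ux, uy, uz;
    if (d < 1e-9) {
        std::normal_distribution<double> g(0.0, 1.0);
        ux = g(rng); uy = g(rng); uz = g(rng);
        double n = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= n; uy /= n; uz /= n;
    } else {
        ux = dx / d; uy = dy / d; uz = dz / d;
    }
    double shift = 0.5 * (d - target); // >0 pull together, <0 push apart
    a[i] += shift * ux;       a[j] -= shift * ux;
    a[i + n2] += shift * uy;  a[j + n2] -= shift * uy;
    a[i + 2 * n2] += shift * uz; a[j + 2 * n2] -= shift * uz;
}

// Staged constraint-projection relaxation of a structure population under
// one-sided harmonic restraints: assigned contacts (d <= Dcontact), chain
// bonds (d <= Dchain), excluded volume (d >= 2 Rex), nuclear envelope
// (|x| <= Rnuc), and an optional harmonic tether to reference coordinates
// (used by the synthetic-data generator).  Each stage perturbs coordinates
// with a Gaussian kick whose amplitude decays to zero, then runs Gauss-Seidel
// projection sweeps; the best (lowest-penalty) coordinates seen per structure
// - including the input - are returned, so the penalty never increases.
// contacts: integer matrix (structure, p, q) 0-based, sorted by structure.
// [[Rcpp::export(name = ".cppRelax")]]
List cppRelax(NumericVector coords, IntegerMatrix chain, IntegerMatrix contacts,
              double Dcontact, double Dchain, double Rex, double Rnuc,
              int nStages, int nSweeps, double kickSigma, double tetherK,
              Nullable<NumericVector> tetherRef, double relTol, int seed,
              double projScale = 0.95) {
    IntegerVector dims = coords.attr("dim");
    int n2 = dims[0], M = dims[2];
    NumericVector out = clone(coords);
    double* x = out.begin();
    const double* ref = nullptr;
    if (tetherRef.isNotNull()) {
        NumericVector tr(tetherRef);
        ref = tr.begin(); // safe: tr shares memory with the SEXP kept alive by caller
    }
    // index contacts by structure
    std::vector<int> cFrom(M + 1, 0);
    for (int k = 0; k < contacts.nrow(); ++k) cFrom[contacts(k, 0) + 1]++;
    for (int m = 0; m < M; ++m) cFrom[m + 1] += cFrom[m];

    NumericVector penBefore(M), penAfter(M);
    IntegerVector violAfter(M), nRes(M);
    double hard = 2.0 * Rex;

    for (int m = 0; m < M; ++m) {
        std::mt19937 rng((unsigned)seed + 977u * (unsigned)m + 1u);
        std::normal_distribution<double> g(0.0, 1.0);
        double* a = x + (std::size_t)3 * n2 * m;
        PenaltyStats st0 = structurePenalty(x, n2, m, chain, Dchain, cFrom,
                                            contacts, Dcontact, Rex, Rnuc, relTol);
        penBefore[m] = st0.penalty;
        std::vector<double> best(a, a + 3 * n2);
        double bestPen = st0.penalty;
        int bestViol = st0.nViol, bestN = st0.nRestraints;

        for (int s = 0; s < nStages; ++s) {
            double sigma = (nStages > 1)
                ? kickSigma * (1.0 - (double)s / (double)(nStages - 1))
                : 0.0;
            if (sigma > 0)
                for (int i = 0; i < 3 * n2; ++i) a[i] += sigma * g(rng);
            for (int sw = 0; sw < nSweeps; ++sw) {
                // contacts
                for (int k = cFrom[m]; k < cFrom[m + 1]; ++k)
                    projectPair(a, n2, contacts(k, 1), contacts(k, 2),
                                projScale * Dcontact, true, rng);
                // chain
                for (int k = 0; k < chain.nrow(); ++k)
                    projectPair(a, n2, chain(k, 0), chain(k, 1),
                                projScale * Dchain, true, rng);
                // excluded volume
                double hard2 = hard * hard;
                for (int i = 0; i < n2; ++i)
                    for (int j = i + 1; j < n2; ++j)
                        if (dist2(x, n2, m, i, j) < hard2)
                            projectPair(a, n2, i, j, hard, false, rng);
                // envelope
                for (int i = 0; i < n2; ++i) {
                    double r = std::sqrt(a[i] * a[i] + a[i + n2] * a[i + n2] +
                                         a[i + 2 * n2] * a[i + 2 * n2]);
                    if (r > Rnuc) {
                        double f = Rnuc / r;
                        a[i] *= f; a[i + n2] *= f; a[i + 2 * n2] *= f;
                    }
                }
                // tether (generator aid, not part of the penalty)
                if (ref && tetherK > 0) {
                    const double* rm = ref + (std::size_t)3 * n2 * m;
                    for (int i = 0; i < 3 * n2; ++i)
                        a[i] += tetherK * (rm[i] - a[i]);
                }
            }
            PenaltyStats st = structurePenalty(x, n2, m, chain, Dchain, cFrom,
                                               contacts, Dcontact, Rex, Rnuc,
                                               relTol);
            if (st.penalty < bestPen) {
                bestPen = st.penalty;
                bestViol = st.nViol;
                bestN = st.nRestraints;
                std::copy(a, a + 3 * n2, best.begin());
            }
        }
        std::copy(best.begin(), best.end(), a);
        penAfter[m] = bestPen;
        violAfter[m] = bestViol;
        nRes[m] = bestN;
    }
    return List::create(_["coords"] = out, _["penaltyBefore"] = penBefore,
                        _["penaltyAfter"] = penAfter,
                        _["violations"] = violAfter,
                        _["nRestraints"] = nRes);
}

// Per-bead, per-structure neighborhood counts within `radius`
// (center-to-center): same-chromosome neighbors (the homolog copy counts as
// intra), other-chromosome neighbors, and trans neighbors labeled A / B
// (labels: 1 = A, 2 = B, 0 = unlabeled; label is per haploid bin).
// [[Rcpp::export(name = ".cppNeighborCounts")]]
List cppNeighborCounts(NumericVector coords, IntegerVector chrom,
                       IntegerVector label, double radius) {
    IntegerVector dims = coords.attr("dim");
    int n2 = dims[0], M = dims[2], N = n2 / 2;
    const double* x = coords.begin();
    double r2 = radius * radius;
    IntegerMatrix nIntra(n2, M), nInter(n2, M), nA(n2, M), nB(n2, M);
    for (int m = 0; m < M; ++m) {
        for (int i = 0; i < n2; ++i) {
            int ci = chrom[i % N];
            for (int j = i + 1; j < n2; ++j) {
                if (dist2(x, n2, m, i, j) >= r2) continue;
                int cj = chrom[j % N];
                if (ci == cj) {
                    nIntra(i, m)++; nIntra(j, m)++;
                } else {
                    nInter(i, m)++; nInter(j, m)++;
                    int li = label[i % N], lj = label[j % N];
                    if (lj == 1) nA(i, m)++; else if (lj == 2) nB(i, m)++;
                    if (li == 1) nA(j, m)++; else if (li == 2) nB(j, m)++;
                }
            }
        }
    }
    return List::create(_["intra"] = nIntra, _["inter"] = nInter,
                        _["A"] = nA, _["B"] = nB);
}

// Edge list (0-based local indices) among a bead subset in one structure.
// [[Rcpp::export(name = ".cppEdges")]]
IntegerMatrix cppEdges(NumericMatrix xyz, double cutoff) {
    int n = xyz.nrow();
    double c2 = cutoff * cutoff;
    std::vector<int> from, to;
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
            double s = 0;
            for (int d = 0; d < 3; ++d) {
                double v = xyz(i, d) - xyz(j, d);
                s += v * v;
            }
            if (s <= c2) { from.push_back(i + 1); to.push_back(j + 1); }
        }
    IntegerMatrix E(from.size(), 2);
    for (int k = 0; k < (int)from.size(); ++k) {
        E(k, 0) = from[k];
        E(k, 1) = to[k];
    }
    return E;
}
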