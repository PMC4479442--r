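#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Multiresolution region merging, connected-component labelling and
// local bare-soil baseline extraction. These are per-pixel algorithms run
// on scenes of ~10^7 pixels, hence compiled code.

namespace {

// Union-find with path halving. Roots are object ids; the survivor of a
// merge is always the smaller id, so root ids are stable and deterministic.
struct UnionFind {
    std::vector<int> parent;
    explicit UnionFind(int n) : parent(n) {
        for (int i = 0; i < n; ++i) parent[i] = i;
    }
    int find(int x) {
        while (parent[x] != x) {
            parent[x] = parent[parent[x]];
            x = parent[x];
        }
        return x;
    }
};

struct EdgeRec {
    int a, b;     // a < b, both roots at aggregation time
    int shared;   // shared boundary length in pixel edges
};

inline uint64_t packPair(int a, int b) {
    if (a > b) std::swap(a, b);
    return (static_cast<uint64_t>(static_cast<uint32_t>(a)) << 32) |
           static_cast<uint32_t>(b);
}

}  // namespace

// Baatz-Schaepe style multiresolution segmentation.
// layers: list of numeric matrices (only layers with weight > 0 are passed);
// lw: their weights; valid: logical matrix of analysable pixels.
// Merge cost f = wcol * dh_color + wshape * dh_shape, accepted while
// f < scale^2, with local mutual-best-fitting candidate selection and ties
// broken towards the smaller object id.
// [[Rcpp::export]]
List cpp_mrs_segment(List layers, NumericVector lw, double scale,
                     double wcol, double wshape, double wsmooth, double wcmp,
                     LogicalMatrix valid, int maxPasses) {
    const int L = layers.size();
    std::vector<const double*> lay(L);
    int nr = valid.nrow(), nc = valid.ncol();
    for (int l = 0; l < L; ++l) {
        NumericMatrix m = layers[l];
        if (m.nrow() != nr || m.ncol() != nc)
            stop("layer dimensions do not match the valid mask");
        lay[l] = &m[0];
    }
    const R_xlen_t n = static_cast<R_xlen_t>(nr) * nc;
    const double thr = scale * scale;

    UnionFind uf(static_cast<int>(n));
    std::vector<int> cnt(n, 0);
    std::vector<int> perim(n, 0);
    std::vector<int16_t> rmin(n), rmax(n), cmin(n), cmax(n);
    // layer-major running sums for mean/sd
    std::vector<std::vector<double>> sumv(L, std::vector<double>(n, 0.0));
    std::vector<std::vector<double>> sumq(L, std::vector<double>(n, 0.0));

    const int* vptr = &valid[0];
    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            R_xlen_t i = r + static_cast<R_xlen_t>(c) * nr;
            if (!vptr[i]) continue;
            cnt[i] = 1;
            perim[i] = 4;
            rmin[i] = rmax[i] = static_cast<int16_t>(r);
            cmin[i] = cmax[i] = static_cast<int16_t>(c);
            for (int l = 0; l < L; ++l) {
                double v = lay[l][i];
                sumv[l][i] = v;
                sumq[l][i] = v * v;
            }
        }
    }

    auto fusionCost = [&](int a, int b, int shared) -> double {
        const double na = cnt[a], nb = cnt[b], nm = na + nb;
        double dcolor = 0.0;
        for (int l = 0; l < L; ++l) {
            double sa = sumv[l][a], sb = sumv[l][b];
            double qa = sumq[l][a], qb = sumq[l][b];
            double va = qa / na - (sa / na) * (sa / na);
            double vb = qb / nb - (sb / nb) * (sb / nb);
            double sm = sa + sb, qm = qa + qb;
            double vm = qm / nm - (sm / nm) * (sm / nm);
            double sda = va > 0 ? std::sqrt(va) : 0.0;
            double sdb = vb > 0 ? std::sqrt(vb) : 0.0;
            double sdm = vm > 0 ? std::sqrt(vm) : 0.0;
            dcolor += lw[l] * (nm * sdm - na * sda - nb * sdb);
        }
        double pm = perim[a] + perim[b] - 2.0 * shared;
        // compactness: n * perimeter / sqrt(n) = perimeter * sqrt(n)
        double dcmp = pm * std::sqrt(nm) - perim[a] * std::sqrt(na) -
                      perim[b] * std::sqrt(nb);
        // smoothness: n * perimeter / bounding-box perimeter
        auto bboxp = [](int16_t r0, int16_t r1, int16_t c0, int16_t c1) {
            return 2.0 * ((r1 - r0 + 1) + (c1 - c0 + 1));
        };
        double bpa = bboxp(rmin[a], rmax[a], cmin[a], cmax[a]);
        double bpb = bboxp(rmin[b], rmax[b], cmin[b], cmax[b]);
        double bpm = bboxp(std::min(rmin[a], rmin[b]), std::max(rmax[a], rmax[b]),
                           std::min(cmin[a], cmin[b]), std::max(cmax[a], cmax[b]));
        double dsmooth = nm * pm / bpm - na * perim[a] / bpa - nb * perim[b] / bpb;
        double dshape = wsmooth * dsmooth + wcmp * dcmp;
        return wcol * dcolor + wshape * dshape;
    };

    std::vector<EdgeRec> edges;
    std::vector<double> bestc(n);
    std::vector<int> bestn(n), bestshared(n);
    bool firstPass = true;
    int pass = 0;

    for (;;) {
        ++pass;
        // 1. aggregate unique neighbour pairs with shared boundary lengths
        if (firstPass) {
            std::vector<uint64_t> raw;
            raw.reserve(2 * static_cast<size_t>(n));
            for (int c = 0; c < nc; ++c) {
                for (int r = 0; r < nr; ++r) {
                    R_xlen_t i = r + static_cast<R_xlen_t>(c) * nr;
                    if (!vptr[i]) continue;
                    if (r + 1 < nr && vptr[i + 1]) raw.push_back(packPair((int)i, (int)(i + 1)));
                    if (c + 1 < nc && vptr[i + nr]) raw.push_back(packPair((int)i, (int)(i + nr)));
                }
            }
            std::sort(raw.begin(), raw.end());
            edges.clear();
            edges.reserve(raw.size());
            for (size_t k = 0; k < raw.size();) {
                size_t j = k;
                while (j < raw.size() && raw[j] == raw[k]) ++j;
                EdgeRec e;
                e.a = static_cast<int>(raw[k] >> 32);
                e.b = static_cast<int>(raw[k] & 0xffffffffu);
                e.shared = static_cast<int>(j - k);
                edges.push_back(e);
                k = j;
            }
            firstPass = false;
        } else {
            // resolve survivors, drop internal edges, re-aggregate shared counts
            std::vector<std::pair<uint64_t, int>> res;
            res.reserve(edges.size());
            for (const EdgeRec& e : edges) {
                int a = uf.find(e.a), b = uf.find(e.b);
                if (a != b) res.emplace_back(packPair(a, b), e.shared);
            }
            std::sort(res.begin(), res.end());
            edges.clear();
            for (size_t k = 0; k < res.size();) {
                size_t j = k;
                int s = 0;
                while (j < res.size() && res[j].first == res[k].first) {
                    s += res[j].second;
                    ++j;
                }
                EdgeRec e;
                e.a = static_cast<int>(res[k].first >> 32);
                e.b = static_cast<int>(res[k].first & 0xffffffffu);
                e.shared = s;
                edges.push_back(e);
                k = j;
            }
        }
        if (edges.empty()) break;

        // 2. best neighbour per object (min cost, ties -> smaller id)
        for (const EdgeRec& e : edges) {
            bestc[e.a] = R_PosInf;
            bestn[e.a] = -1;
            bestc[e.b] = R_PosInf;
            bestn[e.b] = -1;
        }
        for (const EdgeRec& e : edges) {
            double f = fusionCost(e.a, e.b, e.shared);
            if (f < bestc[e.a] || (f == bestc[e.a] && e.b < bestn[e.a])) {
                bestc[e.a] = f;
                bestn[e.a] = e.b;
                bestshared[e.a] = e.shared;
            }
            if (f < bestc[e.b] || (f == bestc[e.b] && e.a < bestn[e.b])) {
                bestc[e.b] = f;
                bestn[e.b] = e.a;
                bestshared[e.b] = e.shared;
            }
        }

        // 3. merge mutual best pairs below threshold, ascending id order
        int merges = 0;
        for (const EdgeRec& e : edges) {
            int i = e.a, j = e.b;  // i < j
            if (uf.parent[i] != i || uf.parent[j] != j) continue;
            if (bestn[i] != j || bestn[j] != i) continue;
            if (!(bestc[i] < thr)) continue;
            // merge j into i (survivor = smaller id)
            uf.parent[j] = i;
            const int shared = bestshared[i];
            perim[i] = perim[i] + perim[j] - 2 * shared;
            cnt[i] += cnt[j];
            rmin[i] = std::min(rmin[i], rmin[j]);
            rmax[i] = std::max(rmax[i], rmax[j]);
            cmin[i] = std::min(cmin[i], cmin[j]);
            cmax[i] = std::max(cmax[i], cmax[j]);
            for (int l = 0; l < L; ++l) {
                sumv[l][i] += sumv[l][j];
                sumq[l][i] += sumq[l][j];
            }
            ++merges;
        }
        if (merges == 0) break;
        if (maxPasses > 0 && pass >= maxPasses) break;
        Rcpp::checkUserInterrupt();
    }

    // relabel roots 1..K in column-major first-occurrence order
    IntegerMatrix labels(nr, nc);
    std::vector<int> newid(n, 0);
    int K = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (!vptr[i]) continue;
        int r = uf.find(static_cast<int>(i));
        if (newid[r] == 0) newid[r] = ++K;
        labels[i] = newid[r];
    }

    IntegerVector oCnt(K), oPerim(K);
    IntegerMatrix oBbox(K, 4);
    NumericMatrix oMean(K, L), oSd(K, L);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (!vptr[i]) continue;
        int r = uf.find(static_cast<int>(i));
        if (uf.parent[r] == r && newid[r] > 0) {
            int k = newid[r] - 1;
            if (oCnt[k] == 0) {
                oCnt[k] = cnt[r];
                oPerim[k] = perim[r];
                oBbox(k, 0) = rmin[r] + 1;  // 1-based rows/cols for R
                oBbox(k, 1) = rmax[r] + 1;
                oBbox(k, 2) = cmin[r] + 1;
                oBbox(k, 3) = cmax[r] + 1;
                for (int l = 0; l < L; ++l) {
                    double mu = sumv[l][r] / cnt[r];
                    double va = sumq[l][r] / cnt[r] - mu * mu;
                    oMean(k, l) = mu;
                    oSd(k, l) = va > 0 ? std::sqrt(va) : 0.0;
                }
            }
        }
    }

    // relabelled unique neighbour pairs (a < b)
    std::vector<uint64_t> epairs;
    epairs.reserve(edges.size());
    for (const EdgeRec& e : edges) {
        int a = newid[uf.find(e.a)], b = newid[uf.find(e.b)];
        if (a != b) epairs.push_back(packPair(a, b));
    }
    std::sort(epairs.begin(), epairs.end());
    epairs.erase(std::unique(epairs.begin(), epairs.end()), epairs.end());
    IntegerMatrix oEdges(epairs.size(), 2);
    for (size_t k = 0; k < epairs.size(); ++k) {
        oEdges(k, 0) = static_cast<int>(epairs[k] >> 32);
        oEdges(k, 1) = static_cast<int>(epairs[k] & 0xffffffffu);
    }

    return List::create(_["labels"] = labels, _["pixel_count"] = oCnt,
                        _["perimeter"] = oPerim, _["bbox"] = oBbox,
                        _["mean"] = oMean, _["sd"] = oSd,
                        _["edges"] = oEdges, _["passes"] = pass);
}

// Connected-component labelling of a boolean mask (4- or 8-connectivity),
// labels 1..K in column-major discovery order.
// [[Rcpp::export]]
IntegerMatrix cpp_cc_label(LogicalMatrix mask, int connectivity) {
    if (connectivity != 4 && connectivity != 8)
        stop("connectivity must be 4 or 8");
    int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix labels(nr, nc);
    std::vector<R_xlen_t> stack;
    int K = 0;
    const int* mp = &mask[0];
    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            R_xlen_t i = r + static_cast<R_xlen_t>(c) * nr;
            if (!mp[i] || labels[i] != 0) continue;
            ++K;
            labels[i] = K;
            stack.push_back(i);
            while (!stack.empty()) {
                R_xlen_t p = stack.back();
                stack.pop_back();
                int pr = static_cast<int>(p % nr), pc = static_cast<int>(p / nr);
                for (int dc = -1; dc <= 1; ++dc) {
                    for (int dr = -1; dr <= 1; ++dr) {
                        if (dr == 0 && dc == 0) continue;
                        if (connectivity == 4 && dr != 0 && dc != 0) continue;
                        int qr = pr + dr, qc = pc + dc;
                        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
                        R_xlen_t q = qr + static_cast<R_xlen_t>(qc) * nr;
                        if (mp[q] && labels[q] == 0) {
                            labels[q] = K;
                            stack.push_back(q);
                        }
                    }
                }
            }
        }
    }
    return labels;
}

// Median DSM elevation of bare-soil pixels within a Chebyshev ring of
// ring_px pixels around each requested object; the ring is widened x2 then
// x4 when it contains no soil. NA when even the widest ring is empty.
// [[Rcpp::export]]
NumericVector cpp_ring_baseline(IntegerMatrix labels, IntegerVector objIds,
                                LogicalMatrix soil, NumericMatrix dsm,
                                int ringPx) {
    int nr = labels.nrow(), nc = labels.ncol();
    const int nid = objIds.size();
    NumericVector out(nid, NA_REAL);
    if (nid == 0) return out;

    // map object id -> output slot
    std::unordered_map<int, int> slot;
    slot.reserve(nid * 2);
    for (int k = 0; k < nid; ++k) slot[objIds[k]] = k;

    // collect pixel indices per requested object
    std::vector<std::vector<R_xlen_t>> pix(nid);
    for (R_xlen_t i = 0; i < static_cast<R_xlen_t>(nr) * nc; ++i) {
        int lab = labels[i];
        if (lab == 0) continue;
        auto it = slot.find(lab);
        if (it != slot.end()) pix[it->second].push_back(i);
    }

    const int widen[3] = {1, 2, 4};
    for (int k = 0; k < nid; ++k) {
        if (pix[k].empty()) continue;
        int r0 = nr, r1 = -1, c0 = nc, c1 = -1;
        for (R_xlen_t p : pix[k]) {
            int pr = static_cast<int>(p % nr), pc = static_cast<int>(p / nr);
            r0 = std::min(r0, pr); r1 = std::max(r1, pr);
            c0 = std::min(c0, pc); c1 = std::max(c1, pc);
        }
        const int Rmaxw = ringPx * widen[2];
        int wr0 = std::max(0, r0 - Rmaxw), wr1 = std::min(nr - 1, r1 + Rmaxw);
        int wc0 = std::max(0, c0 - Rmaxw), wc1 = std::min(nc - 1, c1 + Rmaxw);
        int wnr = wr1 - wr0 + 1, wnc = wc1 - wc0 + 1;
        // dist[j] = Chebyshev distance (in dilation steps) from the object
        std::vector<uint8_t> inObj(static_cast<size_t>(wnr) * wnc, 0);
        for (R_xlen_t p : pix[k]) {
            int pr = static_cast<int>(p % nr) - wr0;
            int pc = static_cast<int>(p / nr) - wc0;
            inObj[pr + static_cast<size_t>(pc) * wnr] = 1;
        }
        std::vector<uint8_t> cur = inObj;
        std::vector<double> vals;
        double baseline = NA_REAL;
        int steps = 0;
        for (int w = 0; w < 3 && ISNAN(baseline); ++w) {
            int target = ringPx * widen[w];
            std::vector<uint8_t> nxt(cur.size());
            for (; steps < target; ++steps) {
                for (int c = 0; c < wnc; ++c) {
                    for (int r = 0; r < wnr; ++r) {
                        size_t j = r + static_cast<size_t>(c) * wnr;
                        uint8_t v = cur[j];
                        if (!v) {
                            for (int dc = -1; dc <= 1 && !v; ++dc) {
                                for (int dr = -1; dr <= 1 && !v; ++dr) {
                                    int qr = r + dr, qc = c + dc;
                                    if (qr < 0 || qr >= wnr || qc < 0 || qc >= wnc) continue;
                                    if (cur[qr + static_cast<size_t>(qc) * wnr]) v = 1;
                                }
                            }
                        }
                        nxt[j] = v;
                    }
                }
                cur.swap(nxt);
            }
            vals.clear();
            for (int c = 0; c < wnc; ++c) {
                for (int r = 0; r < wnr; ++r) {
                    size_t j = r + static_cast<size_t>(c) * wnr;
                    if (!cur[j] || inObj[j]) continue;
                    R_xlen_t gi = (wr0 + r) + static_cast<R_xlen_t>(wc0 + c) * nr;
                    if (soil[gi] && R_finite(dsm[gi])) vals.push_back(dsm[gi]);
                }
            }
            if (!vals.empty()) {
                std::sort(vals.begin(), vals.end());
                size_t m = vals.size();
                baseline = (m % 2 == 1) ? vals[m / 2]
                                        : 0.5 * (vals[m / 2 - 1] + vals[m / 2]);
            }
        }
        out[k] = baseline;
    }
    return out;
}

// Per-object maximum of a layer over labels 1..K; NA where an object has
// no finite pixel.
// [[Rcpp::export]]
NumericVector cpp_zonal_max(IntegerMatrix labels, NumericMatrix layer, int K) {
    NumericVector out(K, NA_REAL);
    R_xlen_t n = static_cast<R_xlen_t>(labels.nrow()) * labels.ncol();
    if (static_cast<R_xlen_t>(layer.nrow()) * layer.ncol() != n)
        stop("layer and labels dimensions differ");
    for (R_xlen_t i = 0; i < n; ++i) {
        int lab = labels[i];
        if (lab <= 0 || lab > K) continue;
        double v = layer[i];
        if (!R_finite(v)) continue;
        if (ISNAN(out[lab - 1]) || v > out[lab - 1]) out[lab - 1] = v;
    }
    return out;
}

// Per-object sums over a layer: returns sum, sum of squares and count for
// labels 1..K (K = max label). Used for zonal statistics on large rasters.
// [[Rcpp::export]]
List cpp_zonal_stats(IntegerMatrix labels, NumericMatrix layer, int K) {
    NumericVector s(K), q(K);
    IntegerVector cnt(K);
    R_xlen_t n = static_cast<R_xlen_t>(labels.nrow()) * labels.ncol();
    if (static_cast<R_xlen_t>(layer.nrow()) * layer.ncol() != n)
        stop("layer and labels dimensions differ");
    for (R_xlen_t i = 0; i < n; ++i) {
        int lab = labels[i];
        if (lab <= 0 || lab > K) continue;
        double v = layer[i];
        if (!R_finite(v)) continue;
        s[lab - 1] += v;
        q[lab - 1] += v * v;
        cnt[lab - 1] += 1;
    }
    return List::create(_["sum"] = s, _["sumsq"] = q, _["count"] = cnt);
}
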