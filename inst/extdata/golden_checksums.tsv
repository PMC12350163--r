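file	md5
auc_matrix.tsv	87dde1239893c91c9f0e16821e7e673f
delta_summary.tsv	9adb25e415ed94d1f1eb92c22dd1ebc0
dependency_counts.tsv	cd6ed85d924e3cb17cf3dfb1471f195e
dependency_origin.tsv	e0511b0986c84d10346ce9b7051ef27e
filter_report.tsv	158b7baa5e4b824ecbf0fcaf2364c486
level_summary.tsv	693a54282c089887171957720afc557b
or_table.tsv	6b95c097382e875da19eebd8d4b55499
peak_dependency.tsv	dab90584d03cf85b09199ac7e4e0782b
per_bin.tsv	1883764021793410e73f0617d298db5a
venn.tsv	08ff635b8c33eddde7512458f6b21f6d
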