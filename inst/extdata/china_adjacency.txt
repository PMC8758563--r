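BeiJing TianJin
BeiJing HeBei
TianJin HeBei
HeBei LiaoNing
HeBei NeiMengGu
HeBei ShanXi
HeBei HeNan
HeBei ShanDong
ShanXi NeiMengGu
ShanXi ShaanXi
ShanXi HeNan
NeiMengGu HeiLongJiang
NeiMengGu JiLin
NeiMengGu LiaoNing
NeiMengGu ShaanXi
NeiMengGu NingXia
NeiMengGu GanSu
LiaoNing JiLin
JiLin HeiLongJiang
ShangHai JiangSu
ShangHai ZheJiang
JiangSu ZheJiang
JiangSu AnHui
JiangSu ShanDong
ZheJiang AnHui
ZheJiang JiangXi
ZheJiang FuJian
AnHui JiangXi
AnHui HuBei
AnHui HeNan
AnHui ShanDong
FuJian JiangXi
FuJian GuangDong
JiangXi GuangDong
JiangXi HuNan
JiangXi HuBei
ShanDong HeNan
HeNan ShaanXi
HeNan HuBei
HuBei ShaanXi
HuBei ChongQing
HuBei HuNan
HuNan ChongQing
HuNan GuiZhou
HuNan GuangXi
HuNan GuangDong
GuangDong GuangXi
GuangDong HaiNan
GuangXi YunNan
GuangXi GuiZhou
ChongQing SiChuan
ChongQing ShaanXi
ChongQing GuiZhou
SiChuan QingHai
SiChuan GanSu
SiChuan ShaanXi
SiChuan GuiZhou
SiChuan YunNan
SiChuan XiZang
GuiZhou YunNan
YunNan XiZang
XiZang XinJiang
XiZang QingHai
ShaanXi GanSu
ShaanXi NingXia
GanSu XinJiang
GanSu QingHai
GanSu NingXia
QingHai XinJiang
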